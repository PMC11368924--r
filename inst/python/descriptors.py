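"""Batch molecular descriptor scorer.

Reads SMILES (one per line) on stdin and writes a TSV on stdout with
columns: smiles, canonical, valid, logp, qed, sa, np. Invalid lines get
valid=0 and NA metric fields. The first output line is a '#' header
recording the rdkit version so callers can pin descriptor provenance.
"""
import sys

from rdkit import Chem, rdBase, RDLogger
from rdkit.Chem import Crippen, QED, RDConfig
import os

RDLogger.DisableLog("rdApp.*")
sys.path.append(os.path.join(RDConfig.RDContribDir, "SA_Score"))
sys.path.append(os.path.join(RDConfig.RDContribDir, "NP_Score"))
import sascorer  # noqa: E402
import npscorer  # noqa: E402
import contextlib  # noqa: E402

# npscorer chats on stdout while loading its model; keep stdout clean for TSV
with contextlib.redirect_stdout(sys.stderr):
    _np_model = npscorer.readNPModel()


def score(smiles):
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        return None
    return (
        Chem.MolToSmiles(mol),
        Crippen.MolLogP(mol),
        QED.qed(mol),
        sascorer.calculateScore(mol),
        npscorer.scoreMol(mol, _np_model),
    )


def main():
    out = sys.stdout
    out.write("#rdkit=%s\n" % rdBase.rdkitVersion)
    out.write("smiles\tcanonical\tvalid\tlogp\tqed\tsa\tnp\n")
    for line in sys.stdin:
        smi = line.strip()
        if not smi:
            continue
        res = score(smi)
        if res is None:
            out.write("%s\t\t0\tNA\tNA\tNA\tNA\n" % smi)
        else:
            can, logp, qed, sa, np_ = res
            out.write(
                "%s\t%s\t1\t%.6f\t%.6f\t%.6f\t%.6f\n"
                % (smi, can, logp, qed, sa, np_)
            )


if __name__ == "__main__":
    main()
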