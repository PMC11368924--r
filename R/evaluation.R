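#' Uniqueness of a generation batch across targets
#'
#' The fraction (as a percentage) of distinct molecules across all target
#' proteins:
#' \deqn{\mathrm{Uniqueness}(\%) =
#'   \frac{\#\,\mathrm{Set}(\bigcup_p \mathrm{Set}(M_p))}
#'        {\#\,\bigcup_p \mathrm{Set}(M_p)} \times 100,}
#' where molecules are first deduplicated within each protein's collection
#' and the denominator concatenates the per-protein deduplicated sets (a
#' multiset union — a true set union would make the metric identically
#' 100). A model that generates the same molecules for different proteins
#' scores low.
#'
#' @param batch A data frame with columns `protein_id` and `smiles` (or
#'   `tokens`).
#' @return Percentage in `(0, 100]`.
#' @examples
#' batch <- tibble::tibble(
#'   protein_id = c("P1", "P1", "P2", "P2"),
#'   smiles = c("A", "B", "B", "C")
#' )
#' uniqueness(batch) # 75
#' @export
uniqueness <- function(batch) {
  batch <- tibble::as_tibble(batch)
  mol_col <- intersect(c("smiles", "tokens"), names(batch))[1]
  if (is.na(mol_col) || !"protein_id" %in% names(batch)) {
    stop("batch needs columns protein_id and smiles (or tokens)",
         call. = FALSE)
  }
  if (nrow(batch) == 0L) {
    stop("cannot compute uniqueness of an empty batch", call. = FALSE)
  }
  per_protein <- split(batch[[mol_col]], batch$protein_id)
  deduped <- lapply(per_protein, unique)
  numerator <- length(unique(unlist(deduped, use.names = FALSE)))
  denominator <- sum(lengths(deduped))
  100 * numerator / denominator
}

#' Best molecule of a Pareto pool
#'
#' The member with the largest reward-vector summation \eqn{\sum_i r_i}
#' (top rankings across every property at its insertion time); ties are
#' broken by canonical token string order for determinism.
#'
#' @param pool A non-empty [pareto_pool()].
#' @return One-row tibble (same columns as `as_tibble(pool)`).
#' @export
select_best <- function(pool) {
  stopifnot(inherits(pool, "pareto_pool"))
  if (pool_size(pool) == 0L) {
    stop("cannot select from an empty pool", call. = FALSE)
  }
  sums <- rowSums(pool$r)
  ord <- order(-sums, pool$tokens)
  tibble::as_tibble(pool)[ord[1], ]
}

#' Molecules that Pareto-dominate a reference
#'
#' Returns the records whose metric vector weakly dominates the
#' reference's with at least one strict improvement (strict dominance),
#' after orienting all metrics higher-is-better. The reference ligand must
#' be scored with the same objective set.
#'
#' @param records Data frame with one column per objective (raw metric
#'   scale) plus any identifier columns.
#' @param reference A one-row data frame or named vector/list with the
#'   same metric columns.
#' @param objectives The [objective_set()] defining names and directions.
#' @return The dominating subset of `records` (possibly zero rows).
#' @export
dominance_report <- function(records, reference, objectives) {
  stopifnot(inherits(objectives, "objective_set"))
  records <- tibble::as_tibble(records)
  nms <- objectives$names
  if (!all(nms %in% names(records))) {
    stop("records are missing metric columns: ",
         paste(setdiff(nms, names(records)), collapse = ", "), call. = FALSE)
  }
  ref <- unlist(as.list(reference)[nms])
  if (length(ref) != objectives$d || anyNA(ref)) {
    stop("reference is missing metric values for the objective set",
         call. = FALSE)
  }
  orient_row <- function(vals) {
    vapply(seq_along(objectives$objectives), function(i) {
      orient_value(vals[[i]], objectives$objectives[[i]])
    }, numeric(1))
  }
  ref_h <- orient_row(ref)
  keep <- vapply(seq_len(nrow(records)), function(i) {
    h <- orient_row(unlist(records[i, nms]))
    dominates(h, ref_h) == "strict"
  }, logical(1))
  records[keep, ]
}

#' Per-objective summary of generated molecules
#'
#' Mean and normal-approximation 95% confidence interval for each metric
#' column, on the raw (un-oriented) reporting scale.
#'
#' @param records Data frame of molecules with numeric metric columns.
#' @param metrics Character vector of columns to summarise (default: all
#'   numeric columns).
#' @return Tibble with columns `metric`, `n`, `mean`, `ci_lo`, `ci_hi`.
#' @export
summarize_metrics <- function(records, metrics = NULL) {
  records <- tibble::as_tibble(records)
  if (is.null(metrics)) {
    metrics <- names(records)[vapply(records, is.numeric, logical(1))]
  }
  stopifnot(length(metrics) >= 1L)
  if (nrow(records) < 2L) {
    stop("need at least two records for a confidence interval", call. = FALSE)
  }
  purrr::map_dfr(metrics, function(m) {
    x <- records[[m]]
    mu <- mean(x)
    half <- stats::qnorm(0.975) * stats::sd(x) / sqrt(length(x))
    tibble::tibble(metric = m, n = length(x), mean = mu,
                   ci_lo = mu - half, ci_hi = mu + half)
  })
}
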