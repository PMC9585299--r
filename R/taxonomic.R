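#' Taxonomic Hill number (effective number of species)
#'
#' Computes the Hill number of order `q` for a relative-abundance vector:
#' \deqn{^qD = \left(\sum_i p_i^q\right)^{1/(1-q)}}{qD = (sum p_i^q)^(1/(1-q))}
#' with the continuous limit \eqn{^1D = \exp(-\sum_i p_i \ln p_i)} (the
#' exponential of Shannon entropy) taken when `q` is within 1e-8 of 1.
#' `q = 0` is species richness, `q = 2` the inverse Simpson concentration.
#' The sum is evaluated in log space so long tails of very rare species do not
#' underflow.
#'
#' @param p numeric vector of relative abundances; all entries strictly
#'   positive and summing to 1 (tolerance 1e-12 relative). Use
#'   [profile_taxonomic()] to go straight from counts.
#' @param q diversity order, a single number >= 0.
#' @return The effective number of equally abundant species, a scalar >= 1.
#' @examples
#' hill_taxonomic(rep(1/8, 8), q = 1)          # 8: equal abundances
#' hill_taxonomic(c(0.5, 0.25, 0.25), q = 2)   # 1 / 0.375
#' @seealso [hill_phylo()], [hill_functional()], [profile_taxonomic()]
#' @export
hill_taxonomic <- function(p, q) {
  p <- validate_abundance(p)
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q)) {
    stopf("`q` must be a single finite number")
  }
  if (q < 0) stopf("`q` must be >= 0, got %g", q)
  if (q == 0) return(as.numeric(length(p)))   # richness, exactly
  lp <- log(p)
  if (abs(q - 1) < Q_ONE_EPS) {
    exp(-sum(p * lp))
  } else {
    exp(logsumexp(q * lp) / (1 - q))
  }
}

# Checks an abundance vector: positive entries, sums to one. Entries that are
# exactly zero are dropped (they carry no abundance mass).
validate_abundance <- function(p) {
  if (!is.numeric(p) || length(p) == 0L) {
    stopf("abundance vector must be a non-empty numeric vector")
  }
  if (any(!is.finite(p)) || any(p < 0)) {
    stopf("abundances must be finite and non-negative")
  }
  p <- p[p > 0]
  if (length(p) == 0L) stopf("abundance vector has zero total abundance")
  if (abs(sum(p) - 1) > 1e-12 * max(1, length(p))) {
    stopf("relative abundances must sum to 1 (got %.15g)", sum(p))
  }
  p
}

#' Taxonomic diversity profile of a community matrix
#'
#' Applies [hill_taxonomic()] plot by plot after converting counts to relative
#' abundances, returning the long-format slice of the diversity profile for
#' the taxonomic attribute.
#'
#' @param cm community matrix: plots in rows, taxa in columns, non-negative
#'   integer counts (see [read_community()]).
#' @param q_list numeric vector of diversity orders (default `c(0, 1, 2)`).
#' @return A data frame with columns `plot`, `attribute` (`"TD"`), `q`,
#'   `value`, one row per plot and order.
#' @export
profile_taxonomic <- function(cm, q_list = c(0, 1, 2)) {
  cm <- validate_community(cm)
  rows <- expand.grid(plot = rownames(cm), q = q_list,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows$attribute <- "TD"
  rows$value <- mapply(function(pl, q) {
    x <- cm[pl, ]
    hill_taxonomic(x[x > 0] / sum(x), q)
  }, rows$plot, rows$q)
  rows[order(rows$plot, rows$q), c("plot", "attribute", "q", "value")]
}
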