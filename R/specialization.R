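# Shannon-scale niche decomposition (TNW = WIC + BIC), Monte Carlo null,
# and the adjusted specialization index E_adj.

.get_counts <- function(matrix) {
  if (inherits(matrix, "diet_matrix")) return(matrix$counts)
  if (is.matrix(matrix) && is.numeric(matrix)) return(matrix)
  stop("expected a diet_matrix or a numeric count matrix", call. = FALSE)
}

.shannon <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# BIC/TNW of a count matrix with known row sums; 0 for degenerate (TNW = 0)
# pools. Uses the exact identity BIC = TNW - WIC. Internal fast path for the
# Monte Carlo loop; no validation.
.bic_tnw_ratio <- function(counts, n_i = rowSums(counts)) {
  N <- sum(n_i)
  q <- colSums(counts) / N
  tnw <- .shannon(q)
  if (tnw <= 0) return(c(ratio = 0, degenerate = 1))
  p <- counts / n_i
  lp <- p
  lp[p > 0] <- log(p[p > 0])
  lp[p == 0] <- 0
  wic <- sum((n_i / N) * -rowSums(p * lp))
  c(ratio = min(max((tnw - wic) / tnw, 0), 1), degenerate = 0)
}

#' Decompose the total niche width of a population
#'
#' On the Shannon (natural-log) scale, the total niche width of a population
#' (TNW, the entropy of the pooled diet proportions) decomposes exactly into
#' a within-individual component (WIC, the item-weighted mean entropy of the
#' individual diets) and a between-individual component (BIC):
#' `TNW = WIC + BIC`. BIC is computed directly as the item-weighted mean
#' Kullback-Leibler divergence of each individual diet from the pooled diet,
#' which is the Shannon mutual information between individual identity
#' (weighted by items per stomach) and prey category; the additive identity
#' then holds to floating-point accuracy rather than by construction. The
#' specialization index `E_obs = BIC/TNW` runs from 0 (every individual's
#' diet matches the pooled diet: pure generalists) to 1 (individuals use
#' disjoint resources: pure specialists).
#'
#' Item counts, not masses, define the proportions: the pooled proportion of
#' category j is its share of all items, and each individual's diet
#' proportions are its item shares, so individuals are weighted by their
#' item totals — the weighting that makes the decomposition exact.
#'
#' @param matrix A `diet_matrix` (typically after [exclude_monocategory()])
#'   or a plain non-negative count matrix with at least two rows, each with
#'   at least one item.
#' @return An object of class `niche_decomposition`: a list with `tnw`,
#'   `wic`, `bic` (nats), `e_obs`, `p_categories` (categories with pooled
#'   count > 0), `n_individuals`, `pooled` (pooled proportions `q`),
#'   `individual_props` (row-wise proportions) and `row_items`.
#' @references Roughgarden's variance decomposition of niche width and its
#'   Shannon-entropy analogue for discrete diet data.
#' @export
#' @examples
#' m <- rbind(a = c(4L, 0L), b = c(0L, 4L))
#' decompose_niche(m)$e_obs  # disjoint diets: 1
decompose_niche <- function(matrix) {
  counts <- .get_counts(matrix)
  if (nrow(counts) < 2) {
    stop("at least 2 individuals are required to decompose the niche width",
         call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  n_i <- rowSums(counts)
  if (any(n_i < 1)) {
    stop("every individual must have at least one prey item", call. = FALSE)
  }
  N <- sum(n_i)
  q <- colSums(counts) / N
  tnw <- .shannon(q)
  p <- counts / n_i
  lp <- p
  lp[p > 0] <- log(p[p > 0])
  lp[p == 0] <- 0
  wic <- sum((n_i / N) * -rowSums(p * lp))
  # KL(p_i || q), item-weighted: mutual information form of BIC
  lq <- matrix(rep(log(pmax(q, .Machine$double.xmin)), each = nrow(p)),
               nrow(p))
  kl_terms <- p * (lp - lq)
  kl_terms[p == 0] <- 0
  bic <- max(sum((n_i / N) * rowSums(kl_terms)), 0)
  e_obs <- if (tnw > 0) min(max(bic / tnw, 0), 1) else 0
  structure(list(tnw = tnw, wic = wic, bic = bic, e_obs = e_obs,
                 p_categories = sum(colSums(counts) > 0),
                 n_individuals = nrow(counts),
                 pooled = q, individual_props = p, row_items = n_i),
            class = "niche_decomposition")
}

#' @export
print.niche_decomposition <- function(x, ...) {
  cat(sprintf("Niche decomposition (%d individuals, %d categories used):\n",
              x$n_individuals, x$p_categories))
  cat(sprintf("  TNW = %.4f nats  (WIC = %.4f + BIC = %.4f)\n",
              x$tnw, x$wic, x$bic))
  cat(sprintf("  E_obs = BIC/TNW = %.4f\n", x$e_obs))
  invisible(x)
}

#' Monte Carlo null ensemble for BIC/TNW
#'
#' Simulates the null hypothesis that every individual samples its diet
#' randomly from the population's shared resource pool: in each replicate,
#' individual i draws its observed item total `n_i` from a multinomial over
#' the observed pooled proportions `q`, and BIC/TNW is recomputed on the
#' resampled matrix. Replicates whose resampled pool collapses to a single
#' category (TNW = 0) contribute a value of 0 and are counted in
#' `degenerate_count` rather than redrawn, since a zero niche width carries
#' zero between-individual variance and redrawing would bias the null mean.
#'
#' The one-tailed p-value toward specialization uses the add-one convention
#' `p = (1 + #\{null >= E_obs\}) / (replicates + 1)`, so it is never zero.
#'
#' @param matrix A `diet_matrix` or count matrix accepted by
#'   [decompose_niche()].
#' @param replicates Number of Monte Carlo replicates (>= 1). Default 999.
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   ensembles.
#' @return An object of class `null_ensemble`: list with `replicates`,
#'   `values` (the null BIC/TNW draws), `e_null` (their mean), `p_value`,
#'   `seed`, `degenerate_count` and the observed `e_obs`.
#' @export
monte_carlo_null <- function(matrix, replicates = 999, seed = NULL) {
  if (!is.numeric(replicates) || length(replicates) != 1 || replicates < 1) {
    stop("replicates must be a single integer >= 1", call. = FALSE)
  }
  replicates <- as.integer(replicates)
  dec <- decompose_niche(matrix)
  counts <- .get_counts(matrix)
  n_i <- dec$row_items
  N <- sum(n_i)
  n_ind <- nrow(counts)
  pos <- which(dec$pooled > 0)
  qp <- dec$pooled[pos]
  np <- length(pos)
  if (!is.null(seed)) set.seed(seed)
  ind_of_item <- rep(seq_len(n_ind), n_i)
  values <- numeric(replicates)
  degenerate <- 0L
  for (r in seq_len(replicates)) {
    # one multinomial draw per individual == iid category draws per item
    cat_of_item <- sample.int(np, N, replace = TRUE, prob = qp)
    cnt <- matrix(tabulate((ind_of_item - 1L) * np + cat_of_item,
                           nbins = n_ind * np),
                  nrow = n_ind, byrow = TRUE)
    v <- .bic_tnw_ratio(cnt, n_i)
    values[r] <- v[[1]]
    degenerate <- degenerate + as.integer(v[[2]])
  }
  p_value <- (1 + sum(values >= dec$e_obs)) / (replicates + 1)
  structure(list(replicates = replicates, values = values,
                 e_null = mean(values), p_value = p_value,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 degenerate_count = degenerate, e_obs = dec$e_obs),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("Monte Carlo null: R = %d replicates (seed %s)\n",
              x$replicates, ifelse(is.na(x$seed), "unset", x$seed)))
  cat(sprintf("  E_null = %.4f; observed E_obs = %.4f; one-tailed p = %.4g\n",
              x$e_null, x$e_obs, x$p_value))
  if (x$degenerate_count > 0) {
    cat(sprintf("  %d degenerate replicate(s) (single-category pool)\n",
                x$degenerate_count))
  }
  invisible(x)
}

#' Adjusted specialization index E_adj
#'
#' Rescales the observed BIC/TNW against its Monte Carlo null mean and the
#' stated population maximum `E_max = 1 - 1/P`, where P is the number of
#' prey categories consumed by the whole population:
#' `E_adj = (E_obs - E_null) / (E_max - E_null)`. The result is not
#' clamped: because BIC/TNW itself can reach 1 while `E_max < 1`, values
#' outside `[0, 1]` are arithmetically possible and are returned as
#' computed (callers flag them).
#'
#' @param e_obs Observed BIC/TNW.
#' @param e_null Null-mean BIC/TNW from [monte_carlo_null()].
#' @param p_categories Integer P >= 2, the number of categories with pooled
#'   count > 0.
#' @return The adjusted index, a single number.
#' @export
#' @examples
#' adjusted_E(0.55, 0.2, 10)  # (0.55 - 0.2) / (0.9 - 0.2) = 0.5
adjusted_E <- function(e_obs, e_null, p_categories) {
  if (!is.numeric(p_categories) || length(p_categories) != 1 ||
      p_categories < 2 || p_categories != round(p_categories)) {
    stop("p_categories must be a single integer >= 2", call. = FALSE)
  }
  e_max <- 1 - 1 / p_categories
  if (abs(e_max - e_null) < 1e-12) {
    stop("E_max equals E_null; the adjusted index is undefined", call. = FALSE)
  }
  (e_obs - e_null) / (e_max - e_null)
}

#' Run the full individual-specialization test
#'
#' Composes [decompose_niche()], [monte_carlo_null()] and [adjusted_E()]
#' into one result: the observed decomposition, the null ensemble, `E_max`,
#' `E_adj` and the one-tailed Monte Carlo p-value for the hypothesis that
#' individuals are more specialized than random sampling from the shared
#' pool would produce. `e_adj_in_range` flags whether `E_adj` landed inside
#' `[0, 1]`; out-of-range values are reported, not truncated.
#'
#' @inheritParams monte_carlo_null
#' @return An object of class `specialization_result`: list with
#'   `decomposition`, `null`, `e_max`, `e_adj`, `e_adj_in_range`.
#' @seealso [specialization_json()] to serialize the result.
#' @export
specialization_test <- function(matrix, replicates = 999, seed = NULL) {
  dec <- decompose_niche(matrix)
  null <- monte_carlo_null(matrix, replicates = replicates, seed = seed)
  e_max <- 1 - 1 / dec$p_categories
  e_adj <- adjusted_E(dec$e_obs, null$e_null, dec$p_categories)
  structure(list(decomposition = dec, null = null, e_max = e_max,
                 e_adj = e_adj,
                 e_adj_in_range = e_adj >= 0 && e_adj <= 1),
            class = "specialization_result")
}

#' @export
print.specialization_result <- function(x, ...) {
  print(x$decomposition)
  cat(sprintf("  E_null = %.4f (R = %d), E_max = 1 - 1/%d = %.4f\n",
              x$null$e_null, x$null$replicates,
              x$decomposition$p_categories, x$e_max))
  cat(sprintf("  E_adj = %.4f%s; Monte Carlo p = %.4g\n", x$e_adj,
              if (x$e_adj_in_range) "" else " [outside 0-1]",
              x$null$p_value))
  invisible(x)
}

#' Serialize a specialization result to a flat list for JSON output
#'
#' @param result A `specialization_result`.
#' @return A named list of scalars:
#'   tnw, wic, bic, e_obs, e_null, e_max, e_adj, p_value, replicates, seed,
#'   p_categories, n_individuals, degenerate_count, e_adj_in_range.
#' @export
specialization_json <- function(result) {
  stopifnot(inherits(result, "specialization_result"))
  d <- result$decomposition
  n <- result$null
  list(tnw = d$tnw, wic = d$wic, bic = d$bic, e_obs = d$e_obs,
       e_null = n$e_null, e_max = result$e_max, e_adj = result$e_adj,
       p_value = n$p_value, replicates = n$replicates, seed = n$seed,
       p_categories = d$p_categories, n_individuals = d$n_individuals,
       degenerate_count = n$degenerate_count,
       e_adj_in_range = result$e_adj_in_range)
}
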