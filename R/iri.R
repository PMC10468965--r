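# Index of Relative Importance (IRI) per prey category.

#' Compute the Index of Relative Importance table for a population
#'
#' For each prey category j in a post-filter analysis set of stomachs,
#' computes the frequency of occurrence `FO_j` (fraction of stomachs
#' containing the category), the numerical share `N_j` (fraction of all prey
#' items), the gravimetric share `W_j` (fraction of total wet mass), the
#' composite index `IRI_j = FO_j * (N_j + W_j)` and its normalization
#' `%IRI_j = IRI_j / sum_k IRI_k`. The ranking and the `%IRI` proportions
#' are invariant to the output scale and to uniform rescaling of masses.
#' All ten vocabulary categories are retained in the table, including zero
#' rows. Computation is at full precision; rounding is left to the report
#' writer.
#'
#' @param matrix A `diet_matrix` from [build_diet_matrix()]; the full
#'   analysis set, before any mono-category exclusion.
#' @param scale `"proportion"` (default; `fo`, `pct_n`, `pct_w`, `pct_iri`
#'   in 0-1) or `"percent"` (all four multiplied by 100; `iri` is then on
#'   the conventional 0-200 percent scale).
#' @return A data frame of class `iri_table` with columns `category`, `fo`,
#'   `pct_n`, `pct_w`, `iri`, `pct_iri`, and attributes `n_stomachs`,
#'   `n_items`, `total_mass`, `scale`.
#' @export
#' @examples
#' d <- make_paperlike_fixture("pondlike", seed = 1)
#' m <- build_diet_matrix(filter_analysis_set(d))
#' head(compute_iri_table(m)[order(-compute_iri_table(m)$pct_iri), ])
compute_iri_table <- function(matrix, scale = c("proportion", "percent")) {
  stopifnot(inherits(matrix, "diet_matrix"))
  scale <- match.arg(scale)
  counts <- matrix$counts
  masses <- matrix$masses
  if (nrow(counts) < 1) stop("empty diet matrix", call. = FALSE)
  n_items <- sum(counts)
  total_mass <- sum(masses)
  if (n_items < 1) stop("diet matrix contains no prey items", call. = FALSE)
  if (total_mass <= 0) {
    stop("total wet mass is zero; the gravimetric share is undefined",
         call. = FALSE)
  }
  n_stomachs <- nrow(counts)
  fo <- colMeans(counts > 0)
  pct_n <- colSums(counts) / n_items
  pct_w <- colSums(masses) / total_mass
  mult <- if (scale == "percent") 100 else 1
  iri <- (fo * mult) * (pct_n * mult + pct_w * mult)
  pct_iri <- if (sum(iri) > 0) iri / sum(iri) else iri
  out <- data.frame(category = colnames(counts),
                    fo = fo * mult, pct_n = pct_n * mult, pct_w = pct_w * mult,
                    iri = iri, pct_iri = pct_iri * mult,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("iri_table", "data.frame"),
            n_stomachs = n_stomachs, n_items = n_items,
            total_mass = total_mass, scale = scale)
}

#' @export
print.iri_table <- function(x, digits = 4, ...) {
  cat(sprintf("IRI table: %d stomachs, %d items, %s g total wet mass (scale: %s)\n",
              attr(x, "n_stomachs"), attr(x, "n_items"),
              format(attr(x, "total_mass")), attr(x, "scale")))
  y <- as.data.frame(x)
  y[-1] <- lapply(y[-1], round, digits = digits)
  print(y[order(-y$pct_iri), ], row.names = FALSE)
  invisible(x)
}

#' Write an IRI table to CSV
#'
#' @param table An `iri_table`.
#' @param path Output CSV path.
#' @param sort Sort rows by descending `pct_iri`? Default `FALSE` (fixed
#'   vocabulary order).
#' @param digits Decimal places for display rounding; `NA` writes full
#'   precision. Default 4.
#' @return Invisibly, the (possibly rounded/sorted) data frame written.
#' @export
write_iri_csv <- function(table, path, sort = FALSE, digits = 4) {
  stopifnot(inherits(table, "iri_table"))
  y <- as.data.frame(table)
  if (isTRUE(sort)) y <- y[order(-y$pct_iri), , drop = FALSE]
  if (!is.na(digits)) y[-1] <- lapply(y[-1], round, digits = digits)
  utils::write.csv(y, path, row.names = FALSE, quote = FALSE)
  invisible(y)
}
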