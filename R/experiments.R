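#' Sweep the initial attractiveness and measure network asymmetry
#'
#' Runs the evolution model over every `(a, b)` combination, `replicates`
#' times each with per-row seeds derived from the master seed, and records
#' the ensemble mean and standard error of the network asymmetry index
#' `<alpha>`. With `a > b` the grown networks favour in-degrees
#' (`<alpha> > 0`) and vice versa; the index grows with the ratio `a / b`
#' and shrinks as both attractiveness values grow at a fixed ratio or
#' difference.
#'
#' @param a_values,b_values Numeric vectors of attractiveness values; the
#'   sweep covers their Cartesian product.
#' @param base A [model_params()] object supplying `n`, `m`, `p` and the
#'   master seed.
#' @param replicates Realizations per row, at least 2.
#' @return A data frame of class `sweep_result` with columns `a`, `b`, `p`,
#'   `n`, `m`, `replicates`, `mean_alpha`, `se_alpha`.
#' @export
asymmetry_sweep <- function(a_values, b_values, base, replicates = 100) {
  stopifnot(inherits(base, "model_params"), replicates >= 2)
  replicates <- as.integer(replicates)
  grid <- expand.grid(a = a_values, b = b_values, KEEP.OUT.ATTRS = FALSE)
  seeds <- withr::with_seed(
    base$seed,
    matrix(sample.int(2147483646L, nrow(grid) * replicates),
           nrow = nrow(grid)))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    alphas <- vapply(seq_len(replicates), function(r) {
      pr <- model_params(base$n, base$m, grid$a[i], grid$b[i], base$p,
                         seeds[i, r])
      mean_asymmetry(simulate_growth(pr))
    }, numeric(1))
    data.frame(a = grid$a[i], b = grid$b[i], p = base$p, n = base$n,
               m = base$m, replicates = replicates,
               mean_alpha = mean(alphas),
               se_alpha = stats::sd(alphas) / sqrt(replicates))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Ensemble-averaged degree distributions of the evolution model
#'
#' Simulates `replicates` realizations at fixed parameters and averages
#' the per-realization in- and out-degree pdfs on the union support
#' `0..k_max` (each realization's pdf is normalized, so the average stays
#' normalized). The shape falls into one of three regimes driven by the
#' attractiveness relative to the mean degree `m / n`: at `a = b = 1` the
#' pdf decays monotonically from the smallest degree; between 1 and the
#' mean degree it peaks left of the mean; at or above the mean degree it
#' peaks at the mean. [classify_degree_regime()] reports which regime an
#' averaged pdf falls in.
#'
#' @param params A [model_params()] object (its seed is the master seed).
#' @param replicates Number of realizations, at least 1.
#' @return An object of class `distribution_experiment`: a list with
#'   `params`, `replicates`, `mean_degree`, data frames `in_pdf` and
#'   `out_pdf` (columns `k`, `p_k`), and the [classify_degree_regime()]
#'   results `regime_in` and `regime_out`.
#' @export
distribution_experiment <- function(params, replicates = 100) {
  stopifnot(inherits(params, "model_params"), replicates >= 1)
  replicates <- as.integer(replicates)
  seeds <- withr::with_seed(params$seed, sample.int(2147483646L, replicates))
  n <- params$n

  add_counts <- function(acc, k) {
    kmax <- max(k)
    if (length(acc) < kmax + 1L)
      acc <- c(acc, numeric(kmax + 1L - length(acc)))
    acc + tabulate(k + 1L, nbins = length(acc)) / n
  }
  acc_in <- numeric(1L)
  acc_out <- numeric(1L)
  for (r in seq_len(replicates)) {
    pr <- model_params(params$n, params$m, params$a, params$b, params$p,
                       seeds[r])
    g <- simulate_growth(pr)
    acc_in <- add_counts(acc_in, igraph::degree(g, mode = "in"))
    acc_out <- add_counts(acc_out, igraph::degree(g, mode = "out"))
  }
  pdf_in <- acc_in / replicates
  pdf_out <- acc_out / replicates
  mean_degree <- params$m / params$n
  structure(list(
    params = params, replicates = replicates, mean_degree = mean_degree,
    in_pdf = data.frame(k = seq_along(pdf_in) - 1L, p_k = pdf_in),
    out_pdf = data.frame(k = seq_along(pdf_out) - 1L, p_k = pdf_out),
    regime_in = classify_degree_regime(seq_along(pdf_in) - 1L, pdf_in,
                                       mean_degree),
    regime_out = classify_degree_regime(seq_along(pdf_out) - 1L, pdf_out,
                                        mean_degree)),
    class = "distribution_experiment")
}

#' Classify the shape regime of an averaged degree pdf
#'
#' Locates the pdf mode as the argmax after a centred moving-average
#' smoothing (default window 3 bins; the raw argmax of a 100-realization
#' average is noisy) and labels the shape: `"monotone_decay"` when the
#' mode sits at the smallest degree, `"peak_at_mean"` when it lies within
#' one bin of the mean degree, otherwise `"peak_below_mean"` or
#' `"peak_above_mean"`.
#'
#' @param k Integer degree support.
#' @param p_k Pdf values on `k`.
#' @param mean_degree The network mean degree `m / n`.
#' @param window Odd moving-average window width in bins.
#' @return A list with `regime` (character label) and `mode` (degree at
#'   the smoothed mode).
#' @export
classify_degree_regime <- function(k, p_k, mean_degree, window = 3L) {
  stopifnot(length(k) == length(p_k), window >= 1L)
  half <- (as.integer(window) - 1L) %/% 2L
  len <- length(p_k)
  sm <- vapply(seq_len(len), function(i)
    mean(p_k[max(1L, i - half):min(len, i + half)]), numeric(1))
  mode_k <- k[which.max(sm)]
  regime <-
    if (mode_k <= min(k)) "monotone_decay"
    else if (abs(mode_k - mean_degree) <= 1) "peak_at_mean"
    else if (mode_k < mean_degree) "peak_below_mean"
    else "peak_above_mean"
  list(regime = regime, mode = mode_k)
}

#' Compare model degree distributions against a reference network
#'
#' Simulates the evolution model with `N` and `M` taken from the reference
#' graph and the supplied attractiveness values, averages the in- and
#' out-degree pdfs over `replicates` realizations, aligns them with the
#' reference pdfs on a shared support, and reports the total-variation
#' distance per direction. The distances are descriptive only — there is
#' no fitted pass/fail criterion.
#'
#' @param reference A non-empty directed igraph graph.
#' @param a,b Initial attractiveness for in- and out-degrees.
#' @param p Edge-removal probability.
#' @param replicates Number of model realizations.
#' @param seed Master integer seed.
#' @return An object of class `connectome_match`: a list with `params`,
#'   `replicates`, aligned tables `in_table` and `out_table` (columns `k`,
#'   `model_p`, `reference_p`) and total-variation distances `tv_in`,
#'   `tv_out` in `[0, 1]`.
#' @export
match_connectome <- function(reference, a, b, p = 0.1, replicates = 100,
                             seed = 1L) {
  stopifnot(igraph::is_igraph(reference), igraph::is_directed(reference),
            igraph::vcount(reference) > 0)
  params <- model_params(igraph::vcount(reference),
                         igraph::ecount(reference), a, b, p, seed)
  sim <- distribution_experiment(params, replicates)

  align <- function(sim_pdf, direction) {
    dd <- degree_distribution(reference, direction)
    kmax <- max(max(sim_pdf$k), max(dd$support))
    model_p <- numeric(kmax + 1L)
    model_p[sim_pdf$k + 1L] <- sim_pdf$p_k
    ref_p <- numeric(kmax + 1L)
    ref_p[dd$support + 1L] <- as.numeric(dd$pdf)
    data.frame(k = 0:kmax, model_p = model_p, reference_p = ref_p)
  }
  tin <- align(sim$in_pdf, "in")
  tout <- align(sim$out_pdf, "out")
  structure(list(params = params, replicates = as.integer(replicates),
                 in_table = tin, out_table = tout,
                 tv_in = 0.5 * sum(abs(tin$model_p - tin$reference_p)),
                 tv_out = 0.5 * sum(abs(tout$model_p - tout$reference_p))),
            class = "connectome_match")
}

#' @export
print.connectome_match <- function(x, ...) {
  cat(sprintf(
    "model vs reference degree distributions (n = %d, m = %d, a = %g, b = %g, p = %g)\n",
    x$params$n, x$params$m, x$params$a, x$params$b, x$params$p))
  cat(sprintf("  total variation: in %.3f, out %.3f (%d realizations)\n",
              x$tv_in, x$tv_out, x$replicates))
  invisible(x)
}
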