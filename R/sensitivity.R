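# Global sensitivity analysis: Latin hypercube sampling over the model
# constants and partial rank correlation coefficients (PRCC) of the
# drug-efficacy ratio, following the two-residual regression formulation.

.sens_params <- c(
  "lambda_c", "d_n", "d_c", "eta", "s_q", "d_q", "s_M", "lambda_Mrho",
  "K_rho", "chi_M", "lambda_MQ", "d_M", "lambda_rho_c", "lambda_rho_R",
  "lambda_rho_M", "d_rho", "lambda_RM", "lambda_Rbeta", "d_R",
  "lambda_beta_c", "lambda_beta_R", "chi_T", "lambda_T12", "k_10M", "d_T",
  "lambda_hc", "lambda_hM", "chi_e", "lambda_e")

#' Default sensitivity design
#'
#' The 29 kinetic constants screened in the global sensitivity analysis,
#' with ranges from half to twofold of their baseline, except the tumor
#' IL-35 production rate `lambda_rho_c`, which spans the far wider interval
#' from the control-scenario value up to three times the high-secretion
#' baseline (the leverage range of the drug).
#'
#' @param p Baseline parameter set (default: the J558-IL-35 preset).
#' @return An `il35_design` tibble with columns `name`, `min`, `baseline`,
#'   `max`, `unit`.
#' @export
sensitivity_design <- function(p = il35_params("J558-IL-35")) {
  tab <- parameter_table()
  base <- unlist(p[.sens_params])
  d <- tibble::tibble(
    name = .sens_params,
    min = base / 2,
    baseline = base,
    max = base * 2,
    unit = tab$unit[match(.sens_params, tab$name)])
  ctrl <- scenario_table()
  lo <- ctrl$value[ctrl$scenario == "J558-Ctrl"]
  d$min[d$name == "lambda_rho_c"] <- lo
  d$max[d$name == "lambda_rho_c"] <- 3 * base[["lambda_rho_c"]]
  class(d) <- c("il35_design", class(d))
  d
}

validate_design <- function(design) {
  need <- c("name", "min", "baseline", "max")
  if (!all(need %in% names(design)))
    rlang::abort("design needs columns name, min, baseline, max")
  ok <- design$min < design$baseline & design$baseline < design$max
  if (!all(ok))
    rlang::abort(paste0("design rows must satisfy min < baseline < max: ",
                        paste(design$name[!ok], collapse = ", ")))
  invisible(TRUE)
}

#' Latin hypercube sample over a design
#'
#' Stratified sampling: for each parameter the range is cut into `N`
#' equal-width strata and exactly one point is drawn uniformly in each,
#' with strata paired across parameters by independent random permutations.
#' Reproducible under `seed`.
#'
#' @param design An `il35_design` (or any tibble with name/min/baseline/max).
#' @param N Number of samples; must exceed the number of parameters plus 2
#'   so the partial-correlation regressions are overdetermined.
#' @param seed Integer seed.
#' @return N x k tibble of parameter values (columns named by parameter).
#' @export
latin_hypercube <- function(design, N, seed = 1L) {
  validate_design(design)
  k <- nrow(design)
  if (N < k + 2) rlang::abort("N must be at least the parameter count + 2")
  set.seed(seed)
  u <- lhs::randomLHS(N, k)   # one point per equal-width stratum per column
  x <- sweep(u, 2, design$max - design$min, `*`)
  x <- sweep(x, 2, design$min, `+`)
  colnames(x) <- design$name
  tibble::as_tibble(x)
}

#' Run the drug-efficacy model over a sample matrix
#'
#' For each sampled parameter set, simulates the treated (continuous dosing)
#' and untreated arms from identical initial conditions and records the
#' tumor-burden ratio at the horizon. Failed solver runs are recorded with
#' `status = "failed"` and an `NA` output, never silently dropped; more than
#' 5 percent failures aborts the analysis.
#'
#' @param samples Tibble from [latin_hypercube()].
#' @param base_params Baseline parameter set to overwrite per row.
#' @param protocol Treatment protocol for the treated arm (default:
#'   continuous dosing at strength 1 for 2 months).
#' @param horizon Evaluation time, day.
#' @param n_cells Grid resolution (reduced by default: the efficacy ratio is
#'   a domain-integrated quantity and converges quickly in the grid).
#' @return Tibble with columns `.row`, `output` (efficacy ratio), `status`.
#' @export
run_design <- function(samples, base_params = il35_params("J558-IL-35"),
                       protocol = treatment_protocol("continuous", A0 = 1),
                       horizon = 14, n_cells = 20) {
  t_out <- c(0, horizon)
  res <- purrr::map_dfr(seq_len(nrow(samples)), function(i) {
    p <- base_params
    p[names(samples)] <- as.list(as.numeric(samples[i, ]))
    out <- tryCatch({
      none <- simulate_tumor(p, t_out, protocol = NULL, n_cells = n_cells)
      drug <- simulate_tumor(p, t_out, protocol = protocol,
                             n_cells = n_cells)
      efficacy_ratio(drug, none, horizon)$ratio
    }, error = function(e) NA_real_)
    tibble::tibble(.row = i,
                   output = out,
                   status = ifelse(is.na(out), "failed", "ok"))
  })
  nfail <- sum(res$status == "failed")
  if (nfail > 0.05 * nrow(samples))
    rlang::abort(paste0(nfail, " of ", nrow(samples),
                        " simulations failed (> 5%)"))
  res
}

partial_rank_cor <- function(X, y) {
  Xr <- apply(X, 2, rank)           # average ranks on ties
  yr <- rank(y)
  k <- ncol(X); N <- nrow(X)
  vapply(seq_len(k), function(j) {
    Z <- cbind(1, Xr[, -j, drop = FALSE])
    rx <- stats::lm.fit(Z, Xr[, j])$residuals
    ry <- stats::lm.fit(Z, yr)$residuals
    if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
    stats::cor(rx, ry)
  }, numeric(1))
}

#' Partial rank correlation coefficients
#'
#' Rank-transforms every input column and the output, then for each
#' parameter correlates the residuals of two regressions on all remaining
#' parameters (the two-residual formulation): the result is the monotone
#' association between that parameter and the output with the others
#' controlled for. P-values use the t transform with `N - 2 - (k - 1)`
#' degrees of freedom.
#'
#' @param samples N x k tibble or matrix of inputs (no constant column).
#' @param outputs Numeric output vector of length N; rows with `NA` output
#'   (failed runs) are excluded pairwise with a recorded count.
#' @return An `il35_prcc` object; see [tidy.il35_prcc()].
#' @export
prcc <- function(samples, outputs) {
  X <- as.matrix(samples)
  keep <- is.finite(outputs)
  X <- X[keep, , drop = FALSE]
  y <- outputs[keep]
  N <- nrow(X); k <- ncol(X)
  if (N <= k + 2) rlang::abort("need N > k + 2 usable rows")
  if (any(apply(X, 2, stats::sd) == 0))
    rlang::abort("constant input column")
  est <- partial_rank_cor(X, y)
  df <- N - 2 - (k - 1)
  tstat <- est * sqrt(df / pmax(1 - est^2, .Machine$double.eps))
  pval <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  structure(
    list(parameter = colnames(X), prcc = est, p_value = pval,
         n = N, k = k, df = df, excluded = sum(!keep)),
    class = "il35_prcc")
}

#' @export
print.il35_prcc <- function(x, ...) {
  cat("<il35_prcc>", x$k, "parameters, N =", x$n,
      if (x$excluded > 0) paste0("(", x$excluded, " failed rows excluded)"),
      "\n")
  print(utils::head(tidy(x), 10))
  invisible(x)
}

#' Tidy a PRCC result
#'
#' @param x An `il35_prcc` object.
#' @param ... Unused.
#' @return Tibble with columns `parameter`, `prcc`, `p_value`, ordered by
#'   decreasing |PRCC|.
#' @method tidy il35_prcc
#' @export
tidy.il35_prcc <- function(x, ...) {
  tibble::tibble(parameter = x$parameter, prcc = x$prcc,
                 p_value = x$p_value) |>
    dplyr::arrange(dplyr::desc(abs(.data$prcc)))
}

#' One-row summary of a PRCC result
#'
#' @param x An `il35_prcc` object.
#' @param ... Unused.
#' @return Tibble with `n`, `k`, `df`, `excluded`, `n_significant` (p < 0.01).
#' @method glance il35_prcc
#' @export
glance.il35_prcc <- function(x, ...) {
  tibble::tibble(n = x$n, k = x$k, df = x$df, excluded = x$excluded,
                 n_significant = sum(x$p_value < 0.01, na.rm = TRUE))
}
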