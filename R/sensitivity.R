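# Global sensitivity analysis: Latin hypercube sampling of parameter space
# and partial rank correlation coefficients of the day-15 tumor burden.

#' Latin hypercube sample of parameter space
#'
#' Draws a stratified Latin hypercube: for each parameter, the unit interval
#' is split into `n` equal-probability strata, one draw is taken per stratum,
#' and strata are permuted independently across parameters
#' (via [lhs::randomLHS()]). Each unit draw is then mapped onto the declared
#' range, either linearly or log-uniformly. Degenerate ranges (`lo == hi`)
#' yield a constant column, flagged and excluded from downstream PRCC.
#'
#' @param ranges Named list; each element `c(lo, hi)` with `lo <= hi`.
#' @param scales Named character vector over the same names, `"log"` or
#'   `"linear"`; a single value is recycled. Log scaling requires `lo > 0`.
#' @param n Number of samples (>= 2).
#' @param seed Integer seed; the design is reproducible from it.
#' @return Object of class `"lhs_design"`: list with `samples` (n x k
#'   matrix), `ranges`, `scales`, `n`, `seed`, and logical `constant` flags.
#' @export
#' @examples
#' d <- lhs_sample(list(k1 = c(0.05, 5)), "log", n = 10, seed = 1)
#' d$samples
lhs_sample <- function(ranges, scales = "log", n, seed) {
  if (!is.list(ranges) || length(ranges) == 0L || is.null(names(ranges))) {
    stop("ranges must be a non-empty named list of c(lo, hi)", call. = FALSE)
  }
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  k <- length(ranges)
  nms <- names(ranges)
  if (length(scales) == 1L) scales <- stats::setNames(rep(scales, k), nms)
  scales <- scales[nms]
  if (anyNA(scales) || !all(scales %in% c("log", "linear"))) {
    stop("scales must be 'log' or 'linear' for every parameter",
         call. = FALSE)
  }
  lo <- vapply(ranges, function(r) r[1L], numeric(1))
  hi <- vapply(ranges, function(r) r[2L], numeric(1))
  if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(lo > hi)) {
    stop("invalid range(s): require finite lo <= hi", call. = FALSE)
  }
  if (any(scales == "log" & lo <= 0 & lo < hi)) {
    bad <- nms[scales == "log" & lo <= 0 & lo < hi]
    stop("log-scaled range(s) must have lo > 0: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  set.seed(as.integer(seed))
  u <- lhs::randomLHS(as.integer(n), k)
  samples <- matrix(NA_real_, n, k, dimnames = list(NULL, nms))
  for (j in seq_len(k)) {
    if (lo[j] == hi[j]) {
      samples[, j] <- lo[j]
    } else if (scales[[j]] == "log") {
      samples[, j] <- exp(log(lo[j]) + u[, j] * (log(hi[j]) - log(lo[j])))
    } else {
      samples[, j] <- lo[j] + u[, j] * (hi[j] - lo[j])
    }
  }
  structure(list(samples = samples, ranges = ranges, scales = scales,
                 n = as.integer(n), seed = as.integer(seed),
                 constant = stats::setNames(lo == hi, nms)),
            class = "lhs_design")
}

#' Partial rank correlation coefficients
#'
#' For each (non-constant) parameter column, all columns and the output are
#' rank-transformed; the ranks of the focal parameter and of the output are
#' each regressed linearly on the ranks of the remaining parameters, and the
#' PRCC is the Pearson correlation of the two residual vectors. Significance
#' uses the t statistic `t = r * sqrt((N - 2 - p) / (1 - r^2))`, where `p` is
#' the number of controlled parameters, with a two-sided p-value on
#' `N - 2 - p` degrees of freedom.
#'
#' @param samples Numeric matrix, one column per parameter (named).
#' @param outputs Numeric vector of model outputs, one per sample row.
#' @param alpha Significance level for the flags (default 0.05, per
#'   parameter). Holm-adjusted flags are reported alongside as a labeled
#'   extra column.
#' @return Object of class `"prcc_result"`: a list whose `table` is a data
#'   frame with columns `parameter`, `prcc`, `p_value`, `significant`,
#'   `p_holm`, `significant_holm`, `constant`.
#' @export
prcc <- function(samples, outputs, alpha = 0.05) {
  samples <- as.matrix(samples)
  if (is.null(colnames(samples))) {
    colnames(samples) <- paste0("x", seq_len(ncol(samples)))
  }
  n <- nrow(samples)
  if (length(outputs) != n) {
    stop("outputs must have one value per sample row", call. = FALSE)
  }
  if (any(!is.finite(outputs))) {
    stop("outputs must be finite", call. = FALSE)
  }
  if (length(unique(outputs)) == 1L) {
    stop("degenerate output: the output vector is constant", call. = FALSE)
  }
  constant <- apply(samples, 2L, function(x) length(unique(x)) == 1L)
  active <- colnames(samples)[!constant]
  k <- length(active)
  if (k == 0L) stop("all parameter columns are constant", call. = FALSE)
  n_ctrl <- k - 1L
  if (n <= n_ctrl + 2L) {
    stop("need more samples than parameters + 2 for PRCC", call. = FALSE)
  }
  rx <- apply(samples[, active, drop = FALSE], 2L, rank)
  ry <- rank(outputs)
  est <- p_val <- stats::setNames(rep(NA_real_, ncol(samples)),
                                  colnames(samples))
  for (j in seq_len(k)) {
    others <- rx[, -j, drop = FALSE]
    if (ncol(others) > 0L) {
      qr_o <- qr(cbind(1, others))
      if (qr_o$rank < ncol(others) + 1L) {
        stop("rank-deficient regression; collinear rank columns among: ",
             paste(active[-j], collapse = ", "), call. = FALSE)
      }
      res_x <- qr.resid(qr_o, rx[, j])
      res_y <- qr.resid(qr_o, ry)
    } else {
      res_x <- rx[, j] - mean(rx[, j])
      res_y <- ry - mean(ry)
    }
    ss_x <- sum(res_x^2)
    if (ss_x <= sqrt(.Machine$double.eps) * sum((rx[, j] - mean(rx[, j]))^2)) {
      stop("rank-deficient regression: ranks of ", active[j],
           " are collinear with the other columns", call. = FALSE)
    }
    r <- sum(res_x * res_y) / sqrt(ss_x * sum(res_y^2))
    r <- max(-1, min(1, r))
    df <- n - 2L - n_ctrl
    tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
    est[active[j]] <- r
    p_val[active[j]] <- 2 * stats::pt(-abs(tstat), df)
  }
  p_holm <- stats::setNames(rep(NA_real_, ncol(samples)), colnames(samples))
  p_holm[active] <- stats::p.adjust(p_val[active], method = "holm")
  tab <- data.frame(
    parameter = colnames(samples),
    prcc = unname(est),
    p_value = unname(p_val),
    significant = unname(!is.na(p_val) & p_val < alpha),
    p_holm = unname(p_holm),
    significant_holm = unname(!is.na(p_holm) & p_holm < alpha),
    constant = unname(constant),
    stringsAsFactors = FALSE
  )
  structure(list(table = tab, n_samples = n, n_controlled = n_ctrl,
                 alpha = alpha),
            class = "prcc_result")
}

#' @export
print.prcc_result <- function(x, ...) {
  cat(sprintf("<prcc_result> %d samples, %d controlled parameters\n",
              x$n_samples, x$n_controlled))
  if (!is.null(x$output)) cat("output:", x$output, "\n")
  tab <- x$table[order(-abs(x$table$prcc)), ]
  tab$prcc <- signif(tab$prcc, 3)
  tab$p_value <- signif(tab$p_value, 3)
  tab$p_holm <- signif(tab$p_holm, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Default sensitivity ranges around the literature baseline
#'
#' Every rate/saturation constant varies log-uniformly within an order of
#' magnitude of its baseline (`[v/10, 10v]`), except the tumor growth rate
#' `a` and inverse carrying capacity `b`, which vary within a factor of two
#' (`[v/2, 2v]`) as the output is far more sensitive to them.
#'
#' @param params Baseline parameter set.
#' @return Named list of `c(lo, hi)` ranges over the 19 model parameters.
#' @export
sensitivity_ranges <- function(params = baseline_parameters()) {
  nms <- setdiff(parameter_names(), "d0")
  out <- lapply(nms, function(nm) {
    v <- params[[nm]]
    if (nm %in% c("a", "b")) c(v / 2, 2 * v) else c(v / 10, 10 * v)
  })
  stats::setNames(out, nms)
}

#' LHS/PRCC sensitivity analysis of the day-15 tumor burden
#'
#' Samples the 19 model parameters (log-uniformly over the
#' [sensitivity_ranges()]), simulates the cold-tumor baseline for each sample
#' with or without a 1e6 CFU intravenous bolus, takes the total tumor burden
#' `T_U + T_I` at day 15 as the output, and computes PRCCs with significance
#' flags. Initial conditions are held fixed at baseline; only parameters are
#' varied. Individual simulation failures are excluded from the analysis
#' with a recorded count; more than 5% failures aborts.
#'
#' @param with_bacteria Logical: inject the 1e6 CFU bolus (`TRUE`) or run the
#'   untreated system (`FALSE`).
#' @param n Number of hypercube samples (500 is the standard design; at
#'   least 30 is recommended for stable signs).
#' @param seed Integer seed for the hypercube.
#' @param settings Integration settings; the default integrates to day 15 on
#'   a coarse reporting grid, sufficient for the terminal burden.
#' @param dose Bolus size when `with_bacteria` (CFU).
#' @param output_day Day at which the burden is evaluated.
#' @return A `"prcc_result"` with extra elements `design`, `outputs`,
#'   `failures` (count) and `output` (description string).
#' @export
run_sensitivity <- function(with_bacteria = TRUE, n = 500, seed = 1,
                            settings = simulation_settings(
                              t_end = output_day, output_step = 0.5,
                              rel_tol = 1e-6),
                            dose = 1e6, output_day = 15) {
  params <- baseline_parameters()
  design <- lhs_sample(sensitivity_ranges(params), scales = "log",
                       n = n, seed = seed)
  ic <- baseline_initial_conditions("intravenous", "cold", 1e6,
                                    if (with_bacteria) dose else 0)
  outputs <- rep(NA_real_, n)
  for (s in seq_len(n)) {
    p_s <- params
    p_s[colnames(design$samples)] <- design$samples[s, ]
    outputs[s] <- tryCatch({
      traj <- simulate_therapy(p_s, ic, settings)
      tot <- traj$states[, "T_U"] + traj$states[, "T_I"]
      tot[length(tot)]
    }, error = function(e) NA_real_)
  }
  failed <- !is.finite(outputs)
  if (mean(failed) > 0.05) {
    stop(sprintf("%d of %d simulations failed (> 5%%); aborting",
                 sum(failed), n), call. = FALSE)
  }
  ok <- !failed
  res <- prcc(design$samples[ok, , drop = FALSE], outputs[ok])
  res$design <- design
  res$outputs <- outputs
  res$failures <- sum(failed)
  res$output <- sprintf("T_U + T_I at day %g (%s bacteria, dose %g CFU)",
                        output_day, if (with_bacteria) "with" else "without",
                        if (with_bacteria) dose else 0)
  res
}
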