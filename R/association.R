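# The pairwise regression screen: one no-intercept OLS per
# (digital marker, clinical measure) pair on standardized columns.

#' Fit one digital-clinical regression
#'
#' Ordinary least squares of the standardized clinical measure on the
#' standardized digital marker with age and a digital-by-age interaction,
#' and — for phone-derived markers — a study-phone indicator and its
#' interaction with the digital marker. Because every main column is
#' z-scored across the population, no intercept is included, and
#' `beta_digital` is the effect of the marker at mean age for own-phone
#' participants. Interaction columns are products of the standardized mains
#' and are deliberately not re-standardized. Rows with a missing value in
#' any variable of this pair are dropped for this pair only.
#'
#' @param d standardized digital marker (z-scores, may contain `NA`)
#' @param y standardized clinical measure
#' @param age standardized age; `NULL` fits the single-predictor model
#'   (whose coefficient then equals the Pearson correlation of two z-scored
#'   columns)
#' @param phone study-phone indicator (own = 0, study = 1)
#' @param include_phone add the phone terms (used for phone-derived markers)?
#' @return list of class `association_result`: `beta_digital`, `se`, `t`,
#'   `p_two_sided` (from a t distribution with `n_complete - n_predictors`
#'   degrees of freedom), `n_complete`, `coefficients`, and `insufficient`
#'   (TRUE when fewer complete rows than predictors + 2; estimates are then
#'   `NA` rather than an error, so one empty marker cannot sink the screen)
#' @export
fit_pair <- function(d, y, age = NULL, phone = NULL, include_phone = FALSE) {
  X <- if (is.null(age)) cbind(d = d) else
    cbind(d = d, age = age, d_x_age = d * age)
  if (include_phone) {
    stopifnot(!is.null(phone))
    X <- cbind(X, phone = as.numeric(phone), d_x_phone = d * as.numeric(phone))
  }
  ok <- complete.cases(X) & !is.na(y)
  X <- X[ok, , drop = FALSE]
  yy <- y[ok]
  n <- nrow(X); p <- ncol(X)
  empty <- list(beta_digital = NA_real_, se = NA_real_, t = NA_real_,
                p_two_sided = NA_real_, n_complete = n,
                coefficients = setNames(rep(NA_real_, p), colnames(X)),
                df = NA_integer_, insufficient = TRUE)
  class(empty) <- "association_result"
  if (n < p + 2) return(empty)
  qrx <- qr(X)
  if (qrx$rank < p) {
    bad <- colnames(X)[qrx$pivot[seq(qrx$rank + 1, p)]]
    stop(sprintf("rank-deficient design: collinear column(s) %s",
                 paste(bad, collapse = ", ")))
  }
  beta <- qr.coef(qrx, yy)
  res <- yy - X %*% beta
  df <- n - p
  sigma2 <- sum(res^2) / df
  R <- qr.R(qrx)
  xtx_inv_piv <- chol2inv(R)
  piv <- qrx$pivot
  xtx_inv <- matrix(0, p, p)
  xtx_inv[piv, piv] <- xtx_inv_piv
  se <- sqrt(sigma2 * diag(xtx_inv))
  names(se) <- colnames(X)
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df)
  out <- list(beta_digital = unname(beta["d"]), se = unname(se["d"]),
              t = unname(tval["d"]), p_two_sided = unname(pval["d"]),
              n_complete = n, coefficients = beta, df = df,
              insufficient = FALSE)
  class(out) <- "association_result"
  out
}

#' @export
print.association_result <- function(x, ...) {
  if (x$insufficient) {
    cat(sprintf("<association_result> insufficient data (n=%d)\n", x$n_complete))
  } else {
    cat(sprintf("<association_result> beta=%.3f (se %.3f), t=%.2f, p=%.4f, n=%d\n",
                x$beta_digital, x$se, x$t, x$p_two_sided, x$n_complete))
  }
  invisible(x)
}

#' Run the full pairwise association screen
#'
#' Fits [fit_pair()] for the Cartesian product of digital markers and
#' clinical measures. Phone-derived markers (distance travelled, intertap
#' mode, messages sent, screen time) receive the study-phone terms; wearable
#' markers do not. Raw two-sided p-values are reported without any multiple
#' testing correction — the screen is exploratory by design.
#'
#' @param markers_z `standardized_matrix` of digital markers (from
#'   [transform_and_standardize()]) or an equivalent data.frame with
#'   `participant_id`
#' @param clinical_z `standardized_matrix` from [prepare_clinical()] (must
#'   carry `age` and `uses_study_phone`)
#' @param digital_vars,clinical_vars variable lists; defaults are the twelve
#'   markers and the fifteen clinical measures in heat-map order
#' @return data.frame, one row per pair: digital_var, clinical_var,
#'   beta_digital, se, t, p_two_sided, n_complete, plus one `beta_*` column
#'   per covariate
#' @export
run_screen <- function(markers_z, clinical_z,
                       digital_vars = names(measure_sources()),
                       clinical_vars = clinical_measures()) {
  md <- if (inherits(markers_z, "standardized_matrix")) markers_z$data else
    markers_z
  cd <- if (inherits(clinical_z, "standardized_matrix")) clinical_z$data else
    clinical_z
  m <- match(md$participant_id, cd$participant_id)
  if (any(is.na(m)))
    stop("markers and clinical tables do not share a participant index")
  cd <- cd[m, , drop = FALSE]
  src <- measure_sources()
  coef_names <- c("d", "age", "d_x_age", "phone", "d_x_phone")
  rows <- list()
  for (dv in digital_vars) {
    inc_phone <- identical(src[[dv]], "phone")
    for (cv in clinical_vars) {
      fit <- fit_pair(md[[dv]], cd[[cv]], cd$age,
                      phone = cd$uses_study_phone, include_phone = inc_phone)
      cf <- setNames(rep(NA_real_, length(coef_names)), coef_names)
      cf[names(fit$coefficients)] <- fit$coefficients
      rows[[length(rows) + 1L]] <- data.frame(
        digital_var = dv, clinical_var = cv,
        beta_digital = fit$beta_digital, se = fit$se, t = fit$t,
        p_two_sided = fit$p_two_sided, n_complete = fit$n_complete,
        insufficient = fit$insufficient,
        beta_age = cf[["age"]], beta_d_x_age = cf[["d_x_age"]],
        beta_phone = cf[["phone"]], beta_d_x_phone = cf[["d_x_phone"]],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

significance_tier <- function(p) {
  ifelse(is.na(p), "ns",
         ifelse(p < 0.01, "p<.01", ifelse(p < 0.05, "p<.05", "ns")))
}

#' Coefficient heat-map matrix
#'
#' Arranges the screen results as clinical measures (rows) by digital
#' markers (columns), with a significance tier per cell and a formatted
#' label (coefficient to two decimals, `*` for p < .05, `**` for p < .01).
#'
#' @param results data.frame from [run_screen()]
#' @param digital_vars,clinical_vars orderings (defaults as in the screen)
#' @return list of class `heatmap_matrix`: `beta`, `tier` and `label`
#'   matrices (rows = clinical, cols = digital)
#' @export
heatmap_matrix <- function(results,
                           digital_vars = names(measure_sources()),
                           clinical_vars = clinical_measures()) {
  digital_vars <- intersect(digital_vars, unique(results$digital_var))
  clinical_vars <- intersect(clinical_vars, unique(results$clinical_var))
  beta <- matrix(NA_real_, length(clinical_vars), length(digital_vars),
                 dimnames = list(clinical_vars, digital_vars))
  tier <- matrix("ns", length(clinical_vars), length(digital_vars),
                 dimnames = dimnames(beta))
  for (i in seq_len(nrow(results))) {
    r <- results[i, ]
    if (!r$clinical_var %in% clinical_vars ||
        !r$digital_var %in% digital_vars) next
    beta[r$clinical_var, r$digital_var] <- r$beta_digital
    tier[r$clinical_var, r$digital_var] <- significance_tier(r$p_two_sided)
  }
  stars <- ifelse(tier == "p<.01", "**", ifelse(tier == "p<.05", "*", ""))
  label <- matrix(paste0(format(round(beta, 2), trim = TRUE,
                                drop0trailing = TRUE), stars),
                  nrow(beta), ncol(beta), dimnames = dimnames(beta))
  label[is.na(beta)] <- ""
  structure(list(beta = beta, tier = tier, label = label),
            class = "heatmap_matrix")
}

#' @export
print.heatmap_matrix <- function(x, ...) {
  cat(sprintf("<heatmap_matrix> %d clinical measures x %d digital markers\n",
              nrow(x$beta), ncol(x$beta)))
  print(x$label, quote = FALSE)
  invisible(x)
}

#' Render the coefficient heat map to a file
#'
#' Diverging palette centred at zero, cell labels with significance stars.
#' Uses \pkg{pheatmap} when installed, otherwise a base-graphics fallback.
#'
#' @param hm a `heatmap_matrix`
#' @param file output image path (`.png`)
#' @param width,height device size in pixels
#' @return `file`, invisibly
#' @export
plot_heatmap <- function(hm, file, width = 1400, height = 900) {
  lim <- max(abs(hm$beta), na.rm = TRUE)
  if (!is.finite(lim) || lim == 0) lim <- 1
  pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(101)
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    grDevices::png(file, width = width, height = height)
    pheatmap::pheatmap(hm$beta, cluster_rows = FALSE, cluster_cols = FALSE,
                       display_numbers = hm$label, color = pal,
                       breaks = seq(-lim, lim, length.out = 102),
                       main = "Digital marker x clinical measure regression coefficients")
    grDevices::dev.off()
  } else {
    grDevices::png(file, width = width, height = height)
    op <- graphics::par(mar = c(10, 12, 3, 2))
    b <- hm$beta[rev(seq_len(nrow(hm$beta))), , drop = FALSE]
    graphics::image(t(b), col = pal, zlim = c(-lim, lim), axes = FALSE,
                    main = "Regression coefficients")
    graphics::axis(1, at = seq(0, 1, length.out = ncol(b)),
                   labels = colnames(b), las = 2, cex.axis = 0.8)
    graphics::axis(2, at = seq(0, 1, length.out = nrow(b)),
                   labels = rownames(b), las = 1, cex.axis = 0.8)
    graphics::par(op)
    grDevices::dev.off()
  }
  invisible(file)
}
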