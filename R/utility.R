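# Health-related quality of life: marginal (GEE) regression of EQ-5D utility
# on remission status, and mapping of state utilities from population norms
# via relative decrements.

#' Fit a linear GEE for utility on remission status
#'
#' Marginal linear regression of EQ-5D utility on time-varying remission
#' status (plus optional baseline covariates), with an exchangeable working
#' correlation over each subject's repeated visits and robust (sandwich)
#' standard errors. Implemented directly: coefficients solve the generalised
#' estimating equations by iteratively reweighted least squares, the common
#' within-subject correlation is estimated from Pearson residual
#' cross-products, and the variance is the usual sandwich
#' `B^-1 (sum_i X_i' V_i^-1 e_i e_i' V_i^-1 X_i) B^-1`.
#'
#' With one visit per subject the estimate reduces exactly to ordinary least
#' squares.
#'
#' @param panel Long tibble with columns `id`, `utility`, `remission`
#'   (logical) and any covariate columns named in `covariates`.
#' @param covariates Character vector of additional regressor columns.
#' @param tol,max_iter Convergence control for the coefficient iteration.
#' @return List of class `remit_gee`: `coefficients`, `robust_se`, `vcov`,
#'   `rho` (working correlation), `estimate`, `se`, `p_value` (for the
#'   remission term), `intercept`, `n_subjects`, `n_obs`.
#' @export
fit_gee_utility <- function(panel, covariates = character(),
                            tol = 1e-10, max_iter = 50) {
  stopifnot(all(c("id", "utility", "remission") %in% names(panel)))
  panel <- panel[stats::complete.cases(
    panel[, c("id", "utility", "remission", covariates)]), ]
  ids <- unique(panel$id)
  if (length(ids) < 2) stop("need at least two subjects")
  if (length(unique(panel$remission)) < 2) {
    stop("remission status does not vary within the panel")
  }
  X <- cbind(`(Intercept)` = 1, remission = as.numeric(panel$remission))
  if (length(covariates) > 0) {
    X <- cbind(X, as.matrix(panel[, covariates, drop = FALSE]))
  }
  y <- panel$utility
  p <- ncol(X)
  g <- match(panel$id, ids)
  n_i <- tabulate(g, nbins = length(ids))

  # For an exchangeable working correlation the estimating equations reduce
  # to cluster-level sums: R_i^-1 = (I - rho/b_i J) / (1 - rho) with
  # b_i = 1 + (n_i - 1) rho, so every sum over clusters is a rowsum().
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  beta <- solve(XtX, Xty)  # OLS start; exact GEE solution when all n_i = 1
  rho <- 0
  cluster_terms <- function(rho, res) {
    a <- 1 - rho
    b <- 1 + (n_i - 1) * rho
    w <- rho / (a * b)
    Sx <- rowsum(X, g)
    Se <- as.numeric(rowsum(res, g))
    list(a = a, w = w, Sx = Sx, Se = Se)
  }
  for (iter in seq_len(max_iter)) {
    res <- as.numeric(y - X %*% beta)
    phi <- sum(res^2) / (length(y) - p)
    Se <- as.numeric(rowsum(res, g))
    Se2 <- as.numeric(rowsum(res^2, g))
    den <- sum(n_i * (n_i - 1)) / 2
    rho <- if (den > p) sum((Se^2 - Se2) / 2) / phi / (den - p) else 0
    rho <- min(max(rho, -1 / max(max(n_i) - 1, 1) + 1e-8), 0.999)
    ct <- cluster_terms(rho, res)
    B <- XtX / ct$a - crossprod(ct$Sx, ct$Sx * ct$w)
    Sy <- as.numeric(rowsum(y, g))
    u <- Xty / ct$a - crossprod(ct$Sx, Sy * ct$w)
    beta_new <- solve(B, u)
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  res <- as.numeric(y - X %*% beta)
  ct <- cluster_terms(rho, res)
  B <- XtX / ct$a - crossprod(ct$Sx, ct$Sx * ct$w)
  Sxe <- rowsum(X * res, g)
  Gi <- Sxe / ct$a - ct$Sx * (ct$w * ct$Se)   # X_i' R_i^-1 e_i, one row per cluster
  M <- crossprod(Gi)
  B_inv <- solve(B)
  V <- B_inv %*% M %*% B_inv
  se <- sqrt(diag(V))
  est <- as.numeric(beta)
  names(est) <- colnames(X)
  z <- est[["remission"]] / se[[2]]
  structure(list(
    coefficients = est, robust_se = setNames(se, colnames(X)), vcov = V,
    rho = rho, estimate = est[["remission"]], se = se[[2]],
    p_value = 2 * pnorm(-abs(z)), intercept = est[["(Intercept)"]],
    n_subjects = length(ids), n_obs = length(y)
  ), class = "remit_gee")
}

#' @export
print.remit_gee <- function(x, ...) {
  cat("Linear GEE (exchangeable working correlation, robust SEs)\n")
  cat(sprintf("  subjects: %d  observations: %d  rho: %.3f\n",
              x$n_subjects, x$n_obs, x$rho))
  cat(sprintf("  remission effect: %.4f (SE %.4f, p = %.4g)\n",
              x$estimate, x$se, x$p_value))
  invisible(x)
}

#' Derive state-utility inputs from a fitted utility regression
#'
#' Maps the regression onto the Markov model's states: the predicted utility
#' with diabetes at the baseline age/sex, compared with the general-population
#' norm at that age/sex, gives a relative decrement for the diabetes state;
#' the remission effect reduces the decrement for the remission state.
#'
#' @param fit A `remit_gee` (or a list with `intercept` and `estimate`).
#' @param norms A [population_norms()] table.
#' @param age Baseline age (default 54).
#' @param fraction_women Cohort sex mix for the blended norm.
#' @return List `dec_diabetes`, `dec_remission`, `baseline_predicted`,
#'   `remission_effect`, `norm_at_entry`.
#' @export
derive_utility_inputs <- function(fit, norms = population_norms(),
                                  age = 54, fraction_women = 0.59) {
  n0 <- fraction_women * norm_lookup(norms, age, "F") +
    (1 - fraction_women) * norm_lookup(norms, age, "M")
  pred_d <- fit$intercept
  dec_d <- (n0 - pred_d) / n0
  dec_r <- dec_d - fit$estimate / n0
  stopifnot(dec_d >= 0, dec_d <= 1)
  list(dec_diabetes = dec_d, dec_remission = dec_r,
       baseline_predicted = pred_d, remission_effect = fit$estimate,
       norm_at_entry = n0)
}

#' State utilities at a given age
#'
#' Population-norm utility at the attained age with the relative decrement of
#' each alive state applied; the death state has utility 0. State utilities
#' never exceed the norm and are monotone in it.
#'
#' @param utilities List with `norms`, `dec_diabetes`, `dec_remission` (as in
#'   [base_case_inputs()]).
#' @param age Attained age (vectorised).
#' @param sex `"F"` or `"M"`.
#' @return Tibble `age`, `sex`, `utility_diabetes`, `utility_remission`.
#' @export
state_utilities <- function(utilities, age, sex) {
  norm <- norm_lookup(utilities$norms, age, sex)
  tibble::tibble(
    age = age, sex = sex,
    utility_diabetes = norm * (1 - utilities$dec_diabetes),
    utility_remission = norm * (1 - utilities$dec_remission)
  )
}
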