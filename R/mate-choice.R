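#' Aggregate mate-choice trials into a weighted choice table
#'
#' For each male and UV treatment, successes are events directed at the
#' comimic model female and failures events at the conspecific model; the
#' binomial weight is their sum. Males missing a treatment are excluded.
#' Zero-event rows are retained with weight 0 (they contribute nothing to
#' the likelihood).
#'
#' @param trials data.frame with columns `male_id`, `treatment`
#'   (`UVplus`/`UVminus`), `target_species` (`comimic_model`/
#'   `conspecific_model`), `approaches`, `courtships`.
#' @param behavior `"approach"`, `"courtship"`, or `"both"` (stacked with
#'   a `behavior` column, for treatment x behavior designs).
#' @return data.frame: `male_id`, `treatment`, (`behavior`,) `successes`,
#'   `failures`, `weight`.
#' @export
build_choice_table <- function(trials, behavior = c("approach", "courtship", "both")) {
  behavior <- match.arg(behavior)
  if (behavior == "both") {
    a <- build_choice_table(trials, "approach"); a$behavior <- "approach"
    b <- build_choice_table(trials, "courtship"); b$behavior <- "courtship"
    return(rbind(a, b))
  }
  col <- if (behavior == "approach") "approaches" else "courtships"
  out <- list()
  for (m in unique(trials$male_id)) {
    tm <- trials[trials$male_id == m, ]
    if (!all(c("UVplus", "UVminus") %in% tm$treatment)) {
      message("male ", m, " missing a treatment; excluded")
      next
    }
    for (tr in c("UVplus", "UVminus")) {
      tt <- tm[tm$treatment == tr, ]
      s <- sum(tt[[col]][tt$target_species == "comimic_model"])
      f <- sum(tt[[col]][tt$target_species == "conspecific_model"])
      out[[length(out) + 1]] <- data.frame(male_id = m, treatment = tr,
                                           successes = s, failures = f,
                                           weight = s + f)
    }
  }
  do.call(rbind, out)
}

#' Weighted binomial GLM by iteratively reweighted least squares
#'
#' Logit-link binomial regression of the proportion of events toward the
#' comimic, weighted by each row's total event count. Fitted by IRLS
#' (convergence when the largest coefficient change is below 1e-10, at
#' most 50 iterations); Wald z = estimate/SE with two-sided normal p.
#'
#' @param table choice table from [build_choice_table()].
#' @param design `"intercept_only"`, `"treatment"`, or
#'   `"treatment_x_behavior"` (requires a `behavior` column).
#' @return object of class `"glm_fit"`: `coefficients`,
#'   `standard_errors`, `z`, `p`, `deviance`, `iterations`, `converged`.
#' @export
fit_weighted_binomial <- function(table,
                                  design = c("treatment", "intercept_only",
                                             "treatment_x_behavior")) {
  design <- match.arg(design)
  tab <- table[table$weight > 0, , drop = FALSE]
  X <- switch(design,
    intercept_only = stats::model.matrix(~1, tab),
    treatment = stats::model.matrix(~factor(treatment, c("UVplus", "UVminus")), tab),
    treatment_x_behavior = {
      if (is.null(tab$behavior)) stop("design needs a 'behavior' column; build the table with behavior = 'both'")
      stats::model.matrix(~factor(treatment, c("UVplus", "UVminus")) *
                            factor(behavior), tab)
    })
  colnames(X) <- sub("factor\\(treatment, c\\(\"UVplus\", \"UVminus\"\\)\\)", "treatment",
                     colnames(X))
  colnames(X) <- sub("factor\\(behavior\\)", "behavior", colnames(X))
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank-deficient after aggregation")
  y <- tab$successes / tab$weight
  w <- tab$weight
  beta <- rep(0, ncol(X))
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(50)) {
    eta <- as.numeric(X %*% beta)
    mu <- stats::plogis(eta)
    v <- mu * (1 - mu)
    W <- w * v
    z <- eta + (y - mu) / v
    fit <- stats::lm.wfit(X, z, W)
    new_beta <- fit$coefficients
    if (any(!is.finite(new_beta))) break   # separation drove weights to zero
    if (max(abs(new_beta - beta)) < 1e-10) {
      beta <- new_beta; converged <- TRUE; break
    }
    beta <- new_beta
  }
  eta <- as.numeric(X %*% beta)
  mu <- stats::plogis(eta)
  XtWX <- crossprod(X, X * (w * mu * (1 - mu)))
  se <- tryCatch(sqrt(diag(solve(XtWX))),
                 error = function(e) rep(NA_real_, ncol(X)))
  dev_terms <- function(k, n, p) {
    ll <- ifelse(k > 0, k * log(k / (n * p)), 0) +
      ifelse(n - k > 0, (n - k) * log((n - k) / (n - n * p)), 0)
    2 * ll
  }
  deviance <- sum(dev_terms(tab$successes, w, mu))
  if (!converged || any(abs(eta) > 30))
    warning("possible separation: fit did not stabilize; estimates unreliable")
  names(beta) <- names(se) <- colnames(X)
  zstat <- beta / se
  structure(list(coefficients = beta, standard_errors = se, z = zstat,
                 p = 2 * stats::pnorm(-abs(zstat)), deviance = deviance,
                 iterations = iter, converged = converged),
            class = "glm_fit")
}

#' Wald test of one GLM term
#'
#' @param fit a `"glm_fit"`.
#' @param term coefficient name.
#' @return list with `z` and two-sided `p`.
#' @export
wald_test <- function(fit, term) {
  if (!term %in% names(fit$coefficients))
    stop("unknown term '", term, "'; terms: ",
         paste(names(fit$coefficients), collapse = ", "))
  list(z = unname(fit$z[term]), p = unname(fit$p[term]))
}
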