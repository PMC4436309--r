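# Random-intercept linear mixed model with containment denominator degrees
# of freedom.  The model y = X beta + Z u + e (u: per-subject intercepts) is
# fitted by profiling the (RE)ML criterion over the single variance ratio
# lambda = var(subject) / var(residual); fixed effects come from GLS at the
# optimum.  Type-III F tests use containment DF: effects constant within
# subject are tested against rank([X Z]) - rank(X) denominator DF, effects
# varying within subject against N - rank([X Z]).

#' Fit a random-intercept linear mixed model
#'
#' Fits `response ~ fixed effects + (1 | subject)` by restricted (default)
#' or full maximum likelihood, profiling the likelihood over the
#' subject-to-residual variance ratio.  Factors are coded with sum-to-zero
#' contrasts so the Type-III tests in [anova()] are well defined.
#'
#' @param formula Fixed-effects formula, e.g.
#'   `width ~ landmark * age + circumference`.
#' @param data Data frame; the `subject` column defines the random
#'   intercept grouping.
#' @param subject Name of the grouping column.
#' @param reml Use REML (`TRUE`, default) or ML.
#' @return A `skull_lmm`: list with `coefficients`, `vcov`, `sigma2`
#'   (residual variance), `sigma2_subject`, `lambda`, `logLik`, `AIC`,
#'   `n_parameters`, `rank_X`, `rank_XZ`, `between` (per-term logical:
#'   constant within subject), `assign`, `term_labels`, `N`, `reml`,
#'   `formula`.
#' @export
fit_lmm <- function(formula, data, subject = "subject_id", reml = TRUE) {
  if (!subject %in% names(data))
    stop("design error: no grouping column '", subject, "'")
  g <- factor(data[[subject]])
  if (nlevels(g) < 2)
    stop("design error: need at least 2 subjects for a random intercept")

  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  fac <- names(mf)[vapply(mf, is.factor, logical(1))]
  contr <- stats::setNames(rep(list("contr.sum"), length(fac)), fac)
  X <- stats::model.matrix(formula, mf,
                           contrasts.arg = if (length(fac)) contr)
  N <- nrow(X)
  asgn <- attr(X, "assign")
  term_labels <- attr(stats::terms(mf), "term.labels")

  ni <- as.vector(table(g))
  gi <- as.integer(g)
  p <- qr(X)$rank
  if (N <= p) stop("design error: more fixed-effect parameters than rows")

  gls <- function(lam) {
    ci <- 1 - 1 / sqrt(1 + lam * ni)
    gm_x <- rowsum(X, g) / ni
    gm_y <- rowsum(y, g) / ni
    Xt <- X - ci[gi] * gm_x[gi, , drop = FALSE]
    yt <- y - ci[gi] * gm_y[gi]
    qx <- qr(Xt)
    if (qx$rank < ncol(Xt))
      stop("conditioning error: fixed-effect design rank deficient under GLS")
    rss <- sum(qr.resid(qx, yt)^2)
    logdet_xtx <- 2 * sum(log(abs(diag(qr.R(qx)))))
    list(qx = qx, yt = yt, rss = rss, logdet_xtx = logdet_xtx,
         logdet_v = sum(log1p(lam * ni)))
  }
  crit <- function(lam) {
    s <- gls(lam)
    if (reml) {
      s2 <- s$rss / (N - p)
      (N - p) * (log(2 * pi * s2) + 1) + s$logdet_v + s$logdet_xtx
    } else {
      s2 <- s$rss / N
      N * (log(2 * pi * s2) + 1) + s$logdet_v
    }
  }
  opt <- stats::optimize(function(ll) crit(exp(ll)), c(-20, 15), tol = 1e-9)
  lam <- exp(opt$minimum)
  c0 <- crit(0)
  if (c0 <= opt$objective) {
    lam <- 0
    dev <- c0
  } else dev <- opt$objective

  s <- gls(lam)
  sigma2 <- s$rss / (if (reml) N - p else N)
  beta <- qr.coef(s$qx, s$yt)
  R <- qr.R(s$qx)
  piv <- s$qx$pivot
  xtx_inv <- chol2inv(R)[order(piv), order(piv), drop = FALSE]
  vc <- sigma2 * xtx_inv
  dimnames(vc) <- list(colnames(X), colnames(X))

  Zm <- stats::model.matrix(~ g - 1)
  rank_XZ <- qr(cbind(X, Zm))$rank

  between <- vapply(seq_along(term_labels), function(tt) {
    cols <- which(asgn == tt)
    all(vapply(cols, function(j) {
      gm <- rowsum(X[, j], g) / ni
      max(abs(X[, j] - gm[gi])) < 1e-8
    }, logical(1)))
  }, logical(1))

  npar <- p + 2  # fixed effects + two variance components
  structure(list(coefficients = beta, vcov = vc, sigma2 = sigma2,
                 sigma2_subject = lam * sigma2, lambda = lam,
                 logLik = -dev / 2, AIC = dev + 2 * npar,
                 n_parameters = npar, rank_X = p, rank_XZ = rank_XZ,
                 between = stats::setNames(between, term_labels),
                 assign = asgn, term_labels = term_labels,
                 N = N, reml = reml, formula = formula,
                 n_subjects = nlevels(g)),
            class = "skull_lmm")
}

#' Type-III F tests with containment denominator degrees of freedom
#'
#' One row per fixed-effect term: Wald Type-III F on the sum-to-zero coded
#' coefficients, with numerator DF the number of estimable contrasts and
#' denominator DF by the containment rule -- `rank([X Z]) - rank(X)` for
#' effects constant within subject (tested at the between-subject stratum),
#' `N - rank([X Z])` for effects varying within subject.
#'
#' @param object A `skull_lmm` fit.
#' @param ... Unused.
#' @return Data frame with columns `effect`, `num_df`, `den_df`, `F_value`,
#'   `p_value`, mirroring a mixed-model ANOVA table.
#' @export
anova.skull_lmm <- function(object, ...) {
  rows <- lapply(seq_along(object$term_labels), function(tt) {
    cols <- which(object$assign == tt)
    b <- object$coefficients[cols]
    V <- object$vcov[cols, cols, drop = FALSE]
    q <- length(cols)
    Fv <- tryCatch(as.numeric(crossprod(b, solve(V, b))) / q,
                   error = function(e) NA_real_)
    ddf <- if (object$between[tt]) object$rank_XZ - object$rank_X
           else object$N - object$rank_XZ
    data.frame(effect = object$term_labels[tt], num_df = q, den_df = ddf,
               F_value = Fv,
               p_value = if (is.na(Fv)) NA_real_
                         else stats::pf(Fv, q, ddf, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname fit_lmm
#' @param object A `skull_lmm`.
#' @param ... Unused.
#' @export
logLik.skull_lmm <- function(object, ...) {
  structure(object$logLik, df = object$n_parameters,
            nobs = object$N, class = "logLik")
}

#' Stepwise AIC selection of mixed-model predictors
#'
#' Forward selection by ML AIC: main effects first, then two-way
#' interactions between the significant (p < `alpha`) included mains,
#' respecting hierarchy.  ML (not REML) likelihoods are compared; the
#' selected model is refitted by REML.
#'
#' @param data Long-format data frame.
#' @param response Response column name (e.g. `"width"`).
#' @param mains Candidate main-effect column names.
#' @param subject Grouping column name.
#' @param alpha Significance threshold for a main to seed interactions.
#' @return List with `fit` (the selected `skull_lmm`, REML), `formula`, and
#'   `trace` (data frame of steps: candidate, AIC, accepted).
#' @export
stepwise_lmm <- function(data, response, mains, subject = "subject_id",
                         alpha = 0.05) {
  terms_in <- character(0)
  make_formula <- function(tr) {
    stats::reformulate(if (length(tr)) tr else "1", response = response)
  }
  fit_ml <- function(tr) fit_lmm(make_formula(tr), data, subject, reml = FALSE)
  current <- fit_ml(terms_in)
  trace <- data.frame(step = 0L, candidate = "(intercept)",
                      AIC = current$AIC, accepted = TRUE,
                      stringsAsFactors = FALSE)
  step_i <- 0L

  forward <- function(candidates) {
    repeat {
      todo <- setdiff(candidates, terms_in)
      if (!length(todo)) break
      fits <- lapply(todo, function(tm) fit_ml(c(terms_in, tm)))
      aics <- vapply(fits, function(f) f$AIC, numeric(1))
      best <- which.min(aics)
      step_i <<- step_i + 1L
      accepted <- aics[best] < current$AIC
      trace <<- rbind(trace, data.frame(step = step_i,
                                        candidate = todo[best],
                                        AIC = aics[best],
                                        accepted = accepted,
                                        stringsAsFactors = FALSE))
      if (!accepted) break
      terms_in <<- c(terms_in, todo[best])
      current <<- fits[[best]]
    }
  }

  forward(mains)

  if (length(terms_in) >= 2) {
    at <- anova(current)
    sig <- at$effect[at$effect %in% terms_in & at$p_value < alpha]
    if (length(sig) >= 2) {
      pairs <- utils::combn(sort(sig), 2)
      inter <- apply(pairs, 2, paste, collapse = ":")
      forward(inter)
    }
  }

  final <- fit_lmm(make_formula(terms_in), data, subject, reml = TRUE)
  list(fit = final, formula = make_formula(terms_in), trace = trace,
       terms = terms_in)
}

#' Long tables for the suture-width and thickness mixed models
#'
#' Builds the analysis tables: one row per subject per landmark, with
#' `age` (months), `circumference` (cm), the landmark label as a factor, and
#' the response (`width`, all 32 suture landmarks, zero widths kept; or
#' `thickness`, the 24 skull-surface landmarks).
#'
#' @param geoms List of aligned `processed_geometry` objects.
#' @param features Feature table from [feature_table()] (same order).
#' @param schema A [skull_schema()].
#' @return Long-format data frame.
#' @export
suture_long_table <- function(geoms, features, schema = skull_schema()) {
  s_lab <- schema$pair_map$mid
  do.call(rbind, lapply(seq_along(geoms), function(i) {
    data.frame(subject_id = features$subject_id[i],
               landmark = factor(s_lab, levels = s_lab),
               age = features$age_months[i],
               circumference = features$circumference_cm[i],
               width = unname(geoms[[i]]$widths[s_lab]),
               stringsAsFactors = FALSE)
  }))
}

#' @rdname suture_long_table
#' @export
thickness_long_table <- function(geoms, features, schema = skull_schema()) {
  b_lab <- schema$labels$label[schema$labels$role == "surface"]
  do.call(rbind, lapply(seq_along(geoms), function(i) {
    data.frame(subject_id = features$subject_id[i],
               landmark = factor(b_lab, levels = b_lab),
               age = features$age_months[i],
               circumference = features$circumference_cm[i],
               thickness = unname(geoms[[i]]$thickness[b_lab]),
               stringsAsFactors = FALSE)
  }))
}
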