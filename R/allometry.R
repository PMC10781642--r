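## GLS machinery under Brownian-motion covariance. The tip covariance matrix
## C (shared path lengths) is Cholesky-factored once; model fits and nested
## F tests are then ordinary least squares in the transformed coordinates.

gls_prep <- function(tree, scalars = NULL) {
  tr <- tree
  if (!is.null(scalars)) tr$edge.length <- tr$edge.length * scalars
  C <- ape::vcv(tr)
  Lc <- tryCatch(chol(C), error = function(e) {
    abort("singular phylogenetic covariance (zero-length duplicate tips?)")
  })
  list(tips = rownames(C), Linv = backsolve(Lc, diag(nrow(C)), transpose = TRUE),
       C = C)
}

## OLS in GLS-transformed coordinates; returns fit pieces
gls_fit <- function(X, y, prep) {
  Xs <- prep$Linv %*% X
  ys <- as.numeric(prep$Linv %*% y)
  qr_ <- qr(Xs)
  if (qr_$rank < ncol(X)) abort("rank-deficient design in GLS fit")
  coef <- qr.coef(qr_, ys)
  res <- ys - as.numeric(Xs %*% coef)
  rss <- sum(res^2)
  XtXi <- chol2inv(qr.R(qr_))
  list(coef = coef, rss = rss, XtXi = XtXi, n = length(ys), p = ncol(X),
       resid_t = res)
}

#' Phylogenetic generalized least squares regression
#'
#' Regression of `y` on `x` with residual covariance proportional to shared
#' phylogenetic path lengths (Brownian motion). Reduces exactly to ordinary
#' least squares on a star phylogeny. Following ontogeny, the neonatal value
#' is the independent variable and the adult value the response in the
#' allometric analyses; both are taken on the natural-log scale upstream.
#'
#' @param data a data frame with one row per species.
#' @param x,y column names (strings) of predictor and response.
#' @param tree a rooted `phylo`; tips are matched to `data[[species_col]]`.
#' @param species_col species identifier column (default `"species"`).
#' @return an object of class `pgls_fit` with coefficients, standard errors,
#'   residual variance (unbiased, df = n - 2), GLS residuals, and the pieces
#'   needed for prediction bands. Methods: [tidy()], [glance()],
#'   [predict()][predict.pgls_fit], [autoplot()].
#' @export
pgls_fit <- function(data, x, y, tree, species_col = "species") {
  mp <- match_and_prune(tree, stats::setNames(data, sub(paste0("^", species_col, "$"), "species", names(data))))
  tab <- mp$table
  if (nrow(tab) < 4) abort("need at least 4 matched species")
  prep <- gls_prep(mp$tree)
  idx <- match(prep$tips, tab$species)
  xv <- tab[[x]][idx]
  yv <- tab[[y]][idx]
  X <- cbind(`(Intercept)` = 1, xv)
  colnames(X) <- c("(Intercept)", x)
  f <- gls_fit(X, yv, prep)
  df <- f$n - f$p
  sigma2 <- f$rss / df
  se <- sqrt(diag(f$XtXi) * sigma2)
  ## GLS residuals on the original scale
  resid <- yv - as.numeric(X %*% f$coef)
  structure(
    list(
      coefficients = setNames(as.numeric(f$coef), colnames(X)),
      se = setNames(as.numeric(se), colnames(X)),
      sigma2 = sigma2, df.residual = df, n = f$n,
      rss = f$rss, XtXi = f$XtXi,
      residuals = setNames(resid, prep$tips),
      data = tibble(species = prep$tips, x = xv, y = yv),
      xname = x, yname = y,
      tree = mp$tree, tip_depth = mean(diag(prep$C)),
      loglik = bm_reg_loglik(f, prep)
    ),
    class = "pgls_fit"
  )
}

bm_reg_loglik <- function(f, prep) {
  n <- f$n
  s2 <- f$rss / n
  ldet <- -2 * sum(log(diag(prep$Linv)))
  -n / 2 * log(2 * pi * s2) - ldet / 2 - n / 2
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS (Brownian motion):", x$yname, "~", x$xname, "\n")
  print(round(rbind(estimate = x$coefficients, se = x$se), 4))
  cat("residual variance:", signif(x$sigma2, 4), "on", x$df.residual, "df\n")
  invisible(x)
}

#' @export
tidy.pgls_fit <- function(x, ...) {
  est <- x$coefficients
  se <- x$se
  tval <- est / se
  tibble(
    term = names(est),
    estimate = as.numeric(est),
    std.error = as.numeric(se),
    statistic = as.numeric(tval),
    p.value = 2 * pt(abs(tval), x$df.residual, lower.tail = FALSE)
  )
}

#' @export
glance.pgls_fit <- function(x, ...) {
  tibble(
    sigma2 = x$sigma2, df.residual = x$df.residual, nobs = x$n,
    logLik = x$loglik
  )
}

#' Confidence and prediction intervals for a PGLS fit
#'
#' Intervals are computed in the GLS-transformed coordinates and mapped back.
#' The prediction interval treats the new species as an independent tip at
#' the mean root-to-tip depth of the fitted tree.
#'
#' @param object a `pgls_fit`.
#' @param newdata optional data frame with a column named as the predictor;
#'   defaults to the fitted data.
#' @param interval `"confidence"` or `"prediction"`.
#' @param level coverage level.
#' @param ... unused.
#' @return a tibble with `fit`, `lwr`, `upr`.
#' @export
predict.pgls_fit <- function(object, newdata = NULL,
                             interval = c("confidence", "prediction"),
                             level = 0.95, ...) {
  interval <- match.arg(interval)
  x0 <- if (is.null(newdata)) object$data$x else newdata[[object$xname]]
  X0 <- cbind(1, x0)
  fit <- as.numeric(X0 %*% object$coefficients)
  vconf <- rowSums((X0 %*% object$XtXi) * X0) * object$sigma2
  v <- if (interval == "prediction") vconf + object$sigma2 * object$tip_depth else vconf
  tq <- qt(1 - (1 - level) / 2, object$df.residual)
  tibble(fit = fit, lwr = fit - tq * sqrt(v), upr = fit + tq * sqrt(v))
}

#' Generalized phylogenetic ANCOVA
#'
#' F-tests comparing nested GLS models under Brownian-motion covariance:
#' a common regression line against group-specific intercepts
#' (`test = "intercept"`), or group-specific intercepts against
#' group-specific intercepts and slopes (`test = "slope_and_intercept"`).
#' Degrees of freedom follow the classical ANCOVA convention (difference in
#' parameter counts).
#'
#' @param data data frame with species rows.
#' @param x,y column names of predictor and response.
#' @param tree a rooted `phylo`.
#' @param groups column name holding the group label per species.
#' @param test which nested comparison to run.
#' @param species_col species identifier column.
#' @return an object of class `pancova`: tibble row with `test`, `F`,
#'   `df1`, `df2`, `p.value`, plus attributes `fits` (null and full model
#'   pieces) and `group_lines` (per-group intercepts and slopes from the
#'   richest model).
#' @export
pancova <- function(data, x, y, tree, groups,
                    test = c("intercept", "slope_and_intercept"),
                    species_col = "species") {
  test <- match.arg(test)
  mp <- match_and_prune(tree, stats::setNames(data, sub(paste0("^", species_col, "$"), "species", names(data))))
  tab <- mp$table
  g <- factor(tab[[groups]])
  if (nlevels(g) < 2) abort("need at least 2 groups")
  if (any(table(g) < 3)) abort("every group needs at least 3 species")
  prep <- gls_prep(mp$tree)
  idx <- match(prep$tips, tab$species)
  xv <- tab[[x]][idx]
  yv <- tab[[y]][idx]
  gv <- g[idx]
  X_common <- cbind(1, xv)
  X_int <- stats::model.matrix(~ gv + xv)
  X_full <- stats::model.matrix(~ gv * xv)
  nested <- switch(test,
    intercept = list(X_common, X_int),
    slope_and_intercept = list(X_int, X_full)
  )
  f0 <- gls_fit(nested[[1]], yv, prep)
  f1 <- gls_fit(nested[[2]], yv, prep)
  df1 <- f1$p - f0$p
  df2 <- f1$n - f1$p
  Fstat <- max(0, (f0$rss - f1$rss) / df1) / (f1$rss / df2)
  pv <- pf(Fstat, df1, df2, lower.tail = FALSE)
  fullf <- gls_fit(X_full, yv, prep)
  cf <- fullf$coef
  lev <- levels(gv)
  ints <- cf[1] + c(0, cf[seq_len(length(lev) - 1) + 1])
  slopes <- cf[length(lev) + 1] +
    c(0, if (length(lev) > 1) cf[(length(lev) + 2):length(cf)] else NULL)
  out <- tibble(
    test = test, F = Fstat, df1 = df1, df2 = df2, p.value = pv
  )
  attr(out, "group_lines") <- tibble(
    group = lev, intercept = as.numeric(ints), slope = as.numeric(slopes)
  )
  class(out) <- c("pancova", class(out))
  out
}

#' @export
tidy.pancova <- function(x, ...) {
  tibble(
    test = x$test, statistic = x$F, df1 = x$df1, df2 = x$df2,
    p.value = x$p.value
  )
}

#' Test whether a single species deviates from its clade's scaling
#'
#' F-test for a species-specific intercept against the line shared by the
#' rest of the clade. A slope cannot be estimated from a single tip, so the
#' test is intercept-only (the species-specific dummy absorbs the species'
#' deviation from the shared line).
#'
#' @inheritParams pancova
#' @param species focal species name.
#' @return a `pancova` object with `test = "single_species"`.
#' @export
single_species_test <- function(data, x, y, tree, species,
                                species_col = "species") {
  mp <- match_and_prune(tree, stats::setNames(data, sub(paste0("^", species_col, "$"), "species", names(data))))
  tab <- mp$table
  hit <- normalize_name(tab$species) == normalize_name(species)
  if (!any(hit)) abort(paste0("species not found: ", species))
  if (sum(!hit) < 4) abort("need at least 4 other species")
  prep <- gls_prep(mp$tree)
  idx <- match(prep$tips, tab$species)
  xv <- tab[[x]][idx]
  yv <- tab[[y]][idx]
  dum <- as.numeric(hit[idx])
  f0 <- gls_fit(cbind(1, xv), yv, prep)
  f1 <- gls_fit(cbind(1, xv, dum), yv, prep)
  df2 <- f1$n - f1$p
  Fstat <- max(0, (f0$rss - f1$rss)) / (f1$rss / df2)
  out <- tibble(
    test = "single_species", F = Fstat, df1 = 1L, df2 = df2,
    p.value = pf(Fstat, 1, df2, lower.tail = FALSE)
  )
  attr(out, "species") <- species
  class(out) <- c("pancova", class(out))
  out
}

#' Decompose a species' allometric departure into neonatal and adult drivers
#'
#' Compares the focal species' change along its terminal branch (from the
#' ancestral states of predictor and response) with the change expected under
#' the reference group's PGLS slope. A positive significant departure means
#' the response (adult value) increased more than the scaling relationship
#' predicts ("adult-driven"); a negative one means the predictor side drove
#' the deviation ("neonate-driven" in the neonatal-vs-adult setting).
#'
#' @inheritParams pancova
#' @param species focal species.
#' @param reference_group species names (or a logical/predicate on the data)
#'   defining the reference clade used for the slope; default: all species
#'   except the focal one.
#' @return a one-row tibble: `delta_x`, `delta_y`, `expected_delta_y`,
#'   `departure`, `se`, `z`, `classification`.
#' @export
driver_decomposition <- function(data, x, y, tree, species,
                                 reference_group = NULL,
                                 species_col = "species") {
  mp <- match_and_prune(tree, stats::setNames(data, sub(paste0("^", species_col, "$"), "species", names(data))))
  tab <- mp$table
  hit <- normalize_name(tab$species) == normalize_name(species)
  if (!any(hit)) abort(paste0("species not found: ", species))
  ref <- reference_group %||% tab$species[!hit]
  fit <- pgls_fit(tab[tab$species %in% c(ref), ], x, y, tree)
  slope <- fit$coefficients[[2]]
  var_slope <- fit$XtXi[2, 2] * fit$sigma2
  ## ancestral states of both traits at the focal species' parent node
  xs <- setNames(tab[[x]], tab$species)
  ys <- setNames(tab[[y]], tab$species)
  tr <- mp$tree
  tip <- which(normalize_name(tr$tip.label) == normalize_name(species))
  pedge <- which(tr$edge[, 2] == tip)
  parent <- tr$edge[pedge, 1]
  ax <- ancestral_states(tr, xs)
  ay <- ancestral_states(tr, ys)
  dx <- xs[[tr$tip.label[tip]]] - ax$estimate[parent]
  dy <- ys[[tr$tip.label[tip]]] - ay$estimate[parent]
  expected_dy <- slope * dx
  departure <- dy - expected_dy
  ## departure variance: slope uncertainty plus residual Brownian motion over
  ## (twice) the terminal branch (the ancestor is estimated, not observed)
  tlen <- tr$edge.length[pedge]
  se <- sqrt(dx^2 * var_slope + fit$sigma2 * 2 * tlen)
  z <- departure / se
  classification <- if (abs(z) < 2) {
    "proportional"
  } else if (departure > 0) {
    "adult-driven"
  } else {
    "neonate-driven"
  }
  tibble(
    species = tr$tip.label[tip],
    delta_x = dx, delta_y = dy, expected_delta_y = expected_dy,
    departure = departure, se = se, z = z,
    classification = classification
  )
}
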