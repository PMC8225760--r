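## Assay mathematics: net BRET and %dBRET arithmetic, surface-expression
## normalisation, saturation / bell / titration curve fitting (unweighted
## least squares on untransformed responses, log-midpoint parameterisation)
## and extra sum-of-squares F-test model selection.

#' Net BRET transformation
#'
#' Subtracts the mean raw BRET ratio of the unlabelled control wells from
#' every labelled well (within condition when several conditions are
#' present) and drops the control rows.
#'
#' @param table assay data.frame with columns `response`, `is_control` and
#'   optionally `condition`.
#' @return the table restricted to labelled rows with net responses.
#' @export
netBret <- function(table) {
    if (!any(table$is_control))
        stop("no control rows: net BRET needs unlabelled control wells")
    conds <- if ("condition" %in% names(table)) table$condition else
        rep("all", nrow(table))
    out <- table[!table$is_control, , drop = FALSE]
    for (cc in unique(conds)) {
        ctrl <- table$response[table$is_control & conds == cc]
        if (length(ctrl) == 0L)
            stop("condition '", cc, "' has no control wells")
        sel <- out$condition == cc | !("condition" %in% names(out))
        out$response[sel] <- out$response[sel] - mean(ctrl)
    }
    rownames(out) <- NULL
    out
}

#' Percent BRET change over basal
#'
#' `(stimulated - basal) / basal * 100`, vectorised.
#'
#' @param stimulated,basal raw BRET ratios; `basal` must be positive.
#' @return percent change.
#' @export
deltaBretPercent <- function(stimulated, basal) {
    if (any(basal <= 0)) stop("basal BRET ratios must be positive")
    (stimulated - basal) / basal * 100
}

#' Vehicle-correct percent BRET changes
#'
#' Subtracts the average vehicle %dBRET from each stimulated %dBRET.
#'
#' @param delta stimulated %dBRET values.
#' @param vehicle_delta vehicle-well %dBRET values.
#' @return corrected %dBRET.
#' @export
vehicleCorrect <- function(delta, vehicle_delta) {
    delta - mean(vehicle_delta)
}

#' Normalise responses by relative surface expression
#'
#' Divides each condition's responses by its surface expression relative to
#' the reference condition, so a mutant expressed at half the reference
#' level has its responses doubled.
#'
#' @param table data.frame with `condition`, `response`,
#'   `surface_expression` (positive, constant within condition).
#' @param reference reference condition (default: first condition).
#' @return the table with normalised responses.
#' @export
normalizeByExpression <- function(table, reference = table$condition[1L]) {
    if (any(table$surface_expression <= 0))
        stop("surface expression must be positive")
    expr <- tapply(table$surface_expression, table$condition, function(v) {
        if (length(unique(v)) != 1L)
            stop("surface expression must be constant within condition")
        v[1L]
    })
    if (!reference %in% names(expr)) stop("unknown reference condition")
    factor <- expr[table$condition] / expr[[reference]]
    table$response <- table$response / as.numeric(factor)
    table
}

#' Dual-luciferase reporter fold change
#'
#' `(firefly / renilla) / vehicle_mean_ratio`.
#'
#' @param firefly,renilla reporter luminescence (renilla positive).
#' @param vehicle_mean_ratio mean firefly/renilla ratio of the vehicle
#'   wells (positive).
#' @return fold change over vehicle.
#' @export
reporterRatio <- function(firefly, renilla, vehicle_mean_ratio) {
    if (any(renilla <= 0)) stop("renilla signal must be positive")
    if (vehicle_mean_ratio <= 0) stop("vehicle mean ratio must be positive")
    (firefly / renilla) / vehicle_mean_ratio
}

.newFitResult <- function(model, fit, coefs, se, flags = character(0)) {
    resid <- stats::residuals(fit)
    new("FitResult", model = model, coefficients = coefs, se = se,
        ss = sum(resid^2), df = as.integer(length(resid) - length(coefs)),
        converged = TRUE, flags = flags)
}

.tryNls <- function(formula, data, starts_list, lower = NULL, upper = NULL) {
    best <- NULL
    ctl <- stats::nls.control(maxiter = 200, warnOnly = FALSE)
    for (st in starts_list) {
        fit <- tryCatch(
            if (is.null(lower))
                stats::nls(formula, data = data, start = st, control = ctl)
            else
                stats::nls(formula, data = data, start = st,
                           algorithm = "port", lower = lower, upper = upper,
                           control = ctl),
            error = function(e) NULL)
        ## Gauss-Newton cannot terminate on exact (zero-residual) data;
        ## the port algorithm can, so retry with it
        if (is.null(fit) && is.null(lower))
            fit <- tryCatch(
                stats::nls(formula, data = data, start = st,
                           algorithm = "port", control = ctl),
                error = function(e) NULL)
        if (!is.null(fit)) {
            ss <- sum(stats::residuals(fit)^2)
            if (is.null(best) || ss < best$ss)
                best <- list(fit = fit, ss = ss)
        }
    }
    if (is.null(best)) stop("nonlinear fit failed to converge from all starts")
    best$fit
}

.seFromFit <- function(fit, names) {
    se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                   error = function(e) rep(NA_real_, length(names)))
    se <- se[names]
    names(se) <- names
    se
}

#' Fit a saturation-binding model
#'
#' Three-parameter hyperbola `y = y0 + A * C / (Kd + C)` or four-parameter
#' Hill law `y = y0 + A * C^h / (Kd^h + C^h)`, parameterised in
#' `pKd = -log10(Kd / M)` and fitted by unweighted least squares on the
#' untransformed responses, with multi-start initialisation of pKd at the
#' observed log-concentration quartiles. The reported affinity SD is the
#' asymptotic standard error of pKd from the parameter covariance. Control
#' rows (if any) are removed via [netBret()] first.
#'
#' @param table assay table with `concentration_M` and `response`.
#' @param n_params 3 or 4 (4 adds the Hill slope).
#' @return A [FitResult-class]; coefficients include `pKd`, `y0`,
#'   `amplitude` and (4-parameter) `hill`.
#' @export
fitSaturation <- function(table, n_params = 3L) {
    if (!n_params %in% c(3L, 4L)) stop("n_params must be 3 or 4")
    if ("is_control" %in% names(table) && any(table$is_control))
        table <- netBret(table)
    d <- data.frame(logC = log10(table$concentration_M), y = table$response)
    if (length(unique(d$logC)) < n_params + 1L)
        stop("need more distinct concentrations than parameters")
    a0 <- max(d$y) - min(d$y)
    pk_starts <- unname(stats::quantile(-d$logC, c(0.25, 0.5, 0.75)))
    if (n_params == 3L) {
        fml <- y ~ y0 + A / (1 + 10^(-(pKd + logC)))
        starts <- lapply(pk_starts, function(pk)
            list(y0 = min(d$y), A = a0, pKd = pk))
        fit <- .tryNls(fml, d, starts)
        cf <- stats::coef(fit)
        coefs <- c(pKd = unname(cf["pKd"]), y0 = unname(cf["y0"]),
                   amplitude = unname(cf["A"]))
        se <- .seFromFit(fit, c("pKd", "y0", "A"))
        names(se) <- c("pKd", "y0", "amplitude")
        model <- "saturation_3p"
    } else {
        fml <- y ~ y0 + A / (1 + 10^(-h * (pKd + logC)))
        starts <- lapply(pk_starts, function(pk)
            list(y0 = min(d$y), A = a0, pKd = pk, h = 1))
        fit <- .tryNls(fml, d, starts)
        cf <- stats::coef(fit)
        coefs <- c(pKd = unname(cf["pKd"]), y0 = unname(cf["y0"]),
                   amplitude = unname(cf["A"]), hill = unname(cf["h"]))
        se <- .seFromFit(fit, c("pKd", "y0", "A", "h"))
        names(se) <- c("pKd", "y0", "amplitude", "hill")
        model <- "saturation_4p"
    }
    flags <- character(0)
    if (coefs[["pKd"]] < min(-d$logC) - 2 || coefs[["pKd"]] > max(-d$logC) + 2)
        flags <- "Kd more than 100x outside the concentration range"
    .newFitResult(model, fit, coefs, se, flags)
}

#' Fit a bell-shaped (biphasic) dose-response model
#'
#' Sum of a rising and a falling logistic over `x = log10(C)`:
#' `y = p0 + (p1-p0)/(1+10^((m1-x)h1)) + (p2-p1)/(1+10^((m2-x)h2))`
#' (asymptote p0 at low, p2 at high concentration; peak near p1 when the
#' midpoints are well separated) with the constraint `m1 <= m2` (enforced
#' by parameterising `m2 = m1 + dm`, `dm >= 0`).
#'
#' @param table assay table with `concentration_M` (or `x` as log10 M) and
#'   `response`; needs at least 7 distinct concentrations.
#' @return A [FitResult-class]; coefficients `p0`, `p1`, `p2`, `m1`, `m2`,
#'   `h1`, `h2`.
#' @export
fitBell <- function(table) {
    x <- if ("concentration_M" %in% names(table))
        log10(table$concentration_M) else table$x
    d <- data.frame(x = x, y = table$response)
    if (length(unique(d$x)) < 7L) stop("need at least 7 distinct concentrations")
    ## m2 is parameterised as m1 + dm with dm >= 0 (port bounds)
    fml <- y ~ p0 + (p1 - p0) / (1 + 10^((m1 - x) * h1)) +
        (p2 - p1) / (1 + 10^(((m1 + dm) - x) * h2))
    qs <- stats::quantile(d$x, c(0.25, 0.5, 0.75))
    starts <- list(
        list(p0 = d$y[which.min(d$x)], p1 = max(d$y),
             p2 = d$y[which.max(d$x)], m1 = qs[[1L]],
             dm = qs[[3L]] - qs[[1L]], h1 = 1, h2 = 1),
        list(p0 = min(d$y), p1 = max(d$y), p2 = min(d$y), m1 = qs[[2L]],
             dm = 1, h1 = 1, h2 = 1))
    lower <- c(p0 = -Inf, p1 = -Inf, p2 = -Inf, m1 = -Inf, dm = 0,
               h1 = 0.05, h2 = 0.05)
    upper <- c(p0 = Inf, p1 = Inf, p2 = Inf, m1 = Inf, dm = Inf,
               h1 = 10, h2 = 10)
    fit <- tryCatch(.tryNls(fml, d, starts, lower = lower, upper = upper),
                    error = function(e) NULL)
    if (is.null(fit)) {
        ## monotone-looking data leave the fall phase unidentifiable; fall
        ## back to a single rising logistic with the fall pushed past the
        ## observed range, and flag the degeneracy
        dm_fix <- diff(range(d$x)) + 2
        fit2 <- .tryNls(
            y ~ p0 + (p1 - p0) / (1 + 10^((m1 - x) * h1)), d,
            list(list(p0 = min(d$y), p1 = max(d$y), m1 = qs[[2L]], h1 = 1)))
        cf2 <- stats::coef(fit2)
        se2 <- .seFromFit(fit2, c("p0", "p1", "m1", "h1"))
        coefs <- c(p0 = unname(cf2["p0"]), p1 = unname(cf2["p1"]),
                   p2 = unname(cf2["p1"]), m1 = unname(cf2["m1"]),
                   m2 = unname(cf2["m1"]) + dm_fix, h1 = unname(cf2["h1"]),
                   h2 = NA_real_)
        se <- c(p0 = se2[["p0"]], p1 = se2[["p1"]], p2 = NA_real_,
                m1 = se2[["m1"]], m2 = NA_real_, h1 = se2[["h1"]],
                h2 = NA_real_)
        resid <- stats::residuals(fit2)
        return(new("FitResult", model = "bell",
                   coefficients = coefs, se = se, ss = sum(resid^2),
                   df = as.integer(length(resid) - 4L), converged = TRUE,
                   flags = "fall phase poorly determined (monotone-looking data)"))
    }
    cf <- stats::coef(fit)
    coefs <- c(p0 = unname(cf["p0"]), p1 = unname(cf["p1"]),
               p2 = unname(cf["p2"]), m1 = unname(cf["m1"]),
               m2 = unname(cf["m1"] + cf["dm"]), h1 = unname(cf["h1"]),
               h2 = unname(cf["h2"]))
    se_raw <- .seFromFit(fit, c("p0", "p1", "p2", "m1", "dm", "h1", "h2"))
    se <- c(p0 = se_raw[["p0"]], p1 = se_raw[["p1"]], p2 = se_raw[["p2"]],
            m1 = se_raw[["m1"]], m2 = NA_real_, h1 = se_raw[["h1"]],
            h2 = se_raw[["h2"]])
    flags <- character(0)
    fall_amp <- abs(coefs[["p2"]] - coefs[["p1"]])
    if (is.na(se_raw[["dm"]]) ||
        fall_amp < 2 * max(se_raw[["p1"]], se_raw[["p2"]], na.rm = TRUE))
        flags <- "fall phase poorly determined (monotone-looking data)"
    res <- .newFitResult("bell", fit, coefs, se, flags)
    ## df must reflect the 7 fitted parameters
    res@df <- as.integer(nrow(d) - 7L)
    res
}

#' Fit and select a titration model (linear vs one-phase association)
#'
#' Fits `y = a + b x` (linear) and
#' `y = Y0 + (P - Y0) (1 - exp(-K x))` (one-phase association) and selects
#' between them with the extra sum-of-squares F-test at `alpha`.
#'
#' @param table assay table with `x` (acceptor dose) and `response`.
#' @param alpha F-test significance level, default 0.05.
#' @return list with `linear` and `one_phase` [FitResult-class] objects,
#'   `F`, `p`, `selected` ("linear"/"one_phase") and `plateau` (the fitted
#'   plateau P when the association model is selected, else NA).
#' @export
fitTitration <- function(table, alpha = 0.05) {
    d <- data.frame(x = table$x, y = table$response)
    if (length(unique(d$x)) < 4L) stop("need at least 4 distinct doses")
    lf <- stats::lm(y ~ x, data = d)
    ## summary() warns on zero-residual (noise-free) data; the SEs are
    ## still well defined for our purposes
    sm <- suppressWarnings(summary(lf)$coefficients)
    lin <- new("FitResult", model = "linear",
               coefficients = c(a = unname(stats::coef(lf)[1L]),
                                b = unname(stats::coef(lf)[2L])),
               se = c(a = sm[1L, 2L], b = sm[2L, 2L]),
               ss = sum(stats::residuals(lf)^2),
               df = as.integer(stats::df.residual(lf)),
               converged = TRUE, flags = character(0))
    one <- .fitOnePhase(d)
    test <- extraSSFTest(lin, one, alpha = alpha)
    sel <- if (test$selected == "complex") "one_phase" else "linear"
    list(linear = lin, one_phase = one, F = test$F, p = test$p,
         selected = sel,
         plateau = if (sel == "one_phase") one@coefficients[["P"]]
                   else NA_real_)
}

## One-phase association by profiling: for fixed K the model
## y = Y0 + (P - Y0)(1 - exp(-K x)) is linear in (Y0, P), so the residual
## SS is minimised exactly by linear least squares and only K needs a 1-D
## search. This always converges, including on (near-)linear data where
## Gauss-Newton diverges toward the K -> 0 boundary.
.fitOnePhase <- function(d) {
    xmax <- max(d$x)
    profSS <- function(logK) {
        g <- 1 - exp(-10^logK * d$x)
        f <- stats::lm.fit(cbind(1, g), d$y)
        sum(f$residuals^2)
    }
    rng <- log10(c(1e-3, 1e3) / xmax)
    grid <- seq(rng[1L], rng[2L], length.out = 41L)
    ss <- vapply(grid, profSS, numeric(1L))
    i <- which.min(ss)
    lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
    opt <- stats::optimize(profSS, c(lo, hi), tol = 1e-8)
    K <- 10^opt$minimum
    g <- 1 - exp(-K * d$x)
    lf <- stats::lm.fit(cbind(1, g), d$y)
    Y0 <- lf$coefficients[1L]
    P <- Y0 + lf$coefficients[2L]
    res <- d$y - (Y0 + (P - Y0) * g)
    n <- nrow(d)
    ssq <- sum(res^2)
    ## asymptotic SEs from the Jacobian at the optimum
    J <- cbind(exp(-K * d$x), g, (P - Y0) * d$x * exp(-K * d$x))
    se <- tryCatch({
        v <- ssq / (n - 3L) * solve(crossprod(J))
        sqrt(diag(v))
    }, error = function(e) rep(NA_real_, 3L))
    new("FitResult", model = "one_phase",
        coefficients = c(Y0 = unname(Y0), P = unname(P), K = K),
        se = c(Y0 = se[1L], P = se[2L], K = se[3L]),
        ss = ssq, df = as.integer(n - 3L), converged = TRUE,
        flags = if (opt$minimum <= rng[1L] + 0.05 ||
                    opt$minimum >= rng[2L] - 0.05)
            "rate constant at search boundary" else character(0))
}

#' Extra sum-of-squares F-test between nested fits
#'
#' `F = ((SS_s - SS_c) / (df_s - df_c)) / (SS_c / df_c)` with p from the F
#' distribution on `(df_s - df_c, df_c)` degrees of freedom; the complex
#' model is selected iff p < alpha. When the complex model does not reduce
#' the residual SS the simple model is selected with F = 0, p = 1.
#'
#' @param simple,complex nested [FitResult-class] objects
#'   (`df_simple > df_complex`).
#' @param alpha significance level, default 0.05.
#' @return list with `F`, `p` and `selected` ("simple"/"complex").
#' @export
extraSSFTest <- function(simple, complex, alpha = 0.05) {
    if (simple@df <= complex@df)
        stop("models are not nested: simple model must have more residual df")
    if (simple@ss < complex@ss)
        return(list(F = 0, p = 1, selected = "simple"))
    df1 <- simple@df - complex@df
    Fval <- ((simple@ss - complex@ss) / df1) / (complex@ss / complex@df)
    p <- stats::pf(Fval, df1, complex@df, lower.tail = FALSE)
    list(F = Fval, p = p,
         selected = if (p < alpha) "complex" else "simple")
}
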