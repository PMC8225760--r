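## Synthetic plate-reader-style assay tables: saturation binding (net-BRET
## style), bell-shaped and one-phase/linear dose-response. Noise is iid
## homoscedastic Normal -- the simplest model consistent with mean +/- SEM
## reporting.

#' Saturation-binding generator specification
#'
#' Receptor presets carry the published BODIPY-cyclopamine affinities:
#' smo_wt pKd 6.87, smo_F643P 5.44, fzd6_wt 6.45, fzd6_P643F 6.28. Default
#' concentrations span pKd +/- 2 log units (10 points), duplicates, with
#' noise SD equal to 5% of the amplitude.
#'
#' @slot pKd -log10 Kd (M).
#' @slot amplitude BRET amplitude at saturation.
#' @slot baseline raw-BRET baseline (the unlabelled-control level).
#' @slot hill Hill slope of the generating law.
#' @slot noise_sd iid Normal noise SD.
#' @slot concentrations ligand concentrations in M.
#' @slot n_replicates replicate wells per concentration.
#' @slot n_controls unlabelled control wells.
#' @slot seed integer RNG seed.
#' @export
setClass("BindingSpec",
    representation(pKd = "numeric", amplitude = "numeric",
                   baseline = "numeric", hill = "numeric",
                   noise_sd = "numeric", concentrations = "numeric",
                   n_replicates = "integer", n_controls = "integer",
                   seed = "integer"))

setValidity("BindingSpec", function(object) {
    if (any(object@concentrations <= 0))
        return("concentrations must be positive")
    if (object@noise_sd < 0) return("noise_sd must be >= 0")
    if (object@n_replicates < 1L) return("need at least one replicate")
    TRUE
})

#' Construct a BindingSpec
#' @param pKd -log10 Kd in molar units.
#' @param amplitude saturating BRET amplitude, default 0.5.
#' @param baseline raw baseline, default 0.1.
#' @param hill Hill slope, default 1.
#' @param noise_sd noise SD, default 5% of the amplitude.
#' @param concentrations molar concentrations; default 10 log-spaced points
#'   spanning pKd +/- 2 log units.
#' @param n_replicates wells per concentration, default 2 (duplicates).
#' @param n_controls unlabelled control wells, default 4.
#' @param seed RNG seed, default 1.
#' @return A [BindingSpec-class].
#' @export
bindingSpec <- function(pKd, amplitude = 0.5, baseline = 0.1, hill = 1,
                        noise_sd = 0.05 * amplitude,
                        concentrations = 10^seq(-pKd - 2, -pKd + 2,
                                                length.out = 10),
                        n_replicates = 2L, n_controls = 4L, seed = 1L) {
    new("BindingSpec", pKd = pKd, amplitude = amplitude, baseline = baseline,
        hill = hill, noise_sd = noise_sd, concentrations = concentrations,
        n_replicates = as.integer(n_replicates),
        n_controls = as.integer(n_controls), seed = as.integer(seed))
}

#' Named binding presets
#' @param name one of "smo_wt", "smo_F643P", "fzd6_wt", "fzd6_P643F".
#' @param seed RNG seed, default 1.
#' @param ... further arguments to [bindingSpec()].
#' @return A [BindingSpec-class].
#' @export
bindingPreset <- function(name = c("smo_wt", "smo_F643P", "fzd6_wt",
                                   "fzd6_P643F"), seed = 1L, ...) {
    name <- match.arg(name)
    pKd <- switch(name, smo_wt = 6.87, smo_F643P = 5.44,
                  fzd6_wt = 6.45, fzd6_P643F = 6.28)
    bindingSpec(pKd = pKd, seed = seed, ...)
}

.withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
    expr
}

#' Generate a noisy saturation-binding table
#'
#' Labelled wells follow
#' `baseline + amplitude * C^h / (Kd^h + C^h) + N(0, noise_sd)`; unlabelled
#' control wells sit at `baseline + N(0, noise_sd)`. With `noise_sd = 0`
#' the responses lie exactly on the curve, and at `C = Kd` (hill 1) the
#' noise-free response is exactly `baseline + amplitude / 2`.
#'
#' @param spec a [BindingSpec-class].
#' @param condition condition label, default "wt".
#' @return data.frame with columns `sample_id`, `condition`,
#'   `concentration_M` (NA for controls), `replicate`, `response`,
#'   `is_control`.
#' @export
generateBindingTable <- function(spec, condition = "wt") {
    Kd <- 10^(-spec@pKd)
    C <- rep(spec@concentrations, each = spec@n_replicates)
    repl <- rep(seq_len(spec@n_replicates), times = length(spec@concentrations))
    mu <- spec@baseline + spec@amplitude * C^spec@hill /
        (Kd^spec@hill + C^spec@hill)
    .withSeed(spec@seed, {
        resp <- mu + stats::rnorm(length(mu), 0, spec@noise_sd)
        ctrl <- spec@baseline + stats::rnorm(spec@n_controls, 0, spec@noise_sd)
    })
    n <- length(C)
    rbind(
        data.frame(sample_id = sprintf("w%03d", seq_len(n)),
                   condition = condition, concentration_M = C,
                   replicate = repl, response = resp, is_control = FALSE,
                   stringsAsFactors = FALSE),
        data.frame(sample_id = sprintf("c%03d", seq_len(spec@n_controls)),
                   condition = condition, concentration_M = NA_real_,
                   replicate = seq_len(spec@n_controls), response = ctrl,
                   is_control = TRUE, stringsAsFactors = FALSE))
}

#' Generate a noisy dose-response or titration table
#'
#' Three generating laws:
#' \describe{
#'   \item{bell}{biphasic rise-then-fall over log10 concentration `x`:
#'     `p0 + (p1-p0)/(1+10^((m1-x)h1)) + (p2-p1)/(1+10^((m2-x)h2))`
#'     (asymptotes p0 at low and p2 at high concentration, peak near p1
#'     for m1 well below m2); output column `concentration_M = 10^x`.}
#'   \item{one_phase}{saturating association over acceptor dose `x`:
#'     `Y0 + (P - Y0) * (1 - exp(-K x))`.}
#'   \item{linear}{`a + b x`.}
#' }
#'
#' @param kind "bell", "one_phase" or "linear".
#' @param params named list of curve parameters (see Details); must include
#'   `x` (log10 molar concentrations for "bell", doses otherwise),
#'   and may include `noise_sd` (default 0) and `n_replicates` (default 2).
#' @param seed RNG seed, default 1.
#' @return data.frame with columns `sample_id`, `condition`,
#'   `concentration_M` (bell) or `x` (dose), `replicate`, `response`,
#'   `is_control`.
#' @export
generateDoseResponse <- function(kind = c("bell", "one_phase", "linear"),
                                 params, seed = 1L) {
    kind <- match.arg(kind)
    noise_sd <- if (is.null(params$noise_sd)) 0 else params$noise_sd
    n_rep <- if (is.null(params$n_replicates)) 2L else
        as.integer(params$n_replicates)
    x <- rep(params$x, each = n_rep)
    repl <- rep(seq_len(n_rep), times = length(params$x))
    mu <- switch(kind,
        bell = params$p0 +
            (params$p1 - params$p0) /
                (1 + 10^((params$m1 - x) * params$h1)) +
            (params$p2 - params$p1) /
                (1 + 10^((params$m2 - x) * params$h2)),
        one_phase = params$Y0 + (params$P - params$Y0) *
            (1 - exp(-params$K * x)),
        linear = params$a + params$b * x)
    resp <- .withSeed(seed, mu + stats::rnorm(length(mu), 0, noise_sd))
    out <- data.frame(sample_id = sprintf("w%03d", seq_along(x)),
                      condition = kind, replicate = repl, response = resp,
                      is_control = FALSE, stringsAsFactors = FALSE)
    if (kind == "bell") out$concentration_M <- 10^x else out$x <- x
    out
}
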