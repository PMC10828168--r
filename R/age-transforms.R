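#' Relative age
#'
#' Relative age is chronological age divided by the species' maximum lifespan,
#' so it takes values in \[0, 1\] for animals that do not outlive the recorded
#' species maximum. Values above 1 are permitted (an individual older than the
#' registry maximum) and raise a warning rather than an error.
#'
#' @param age_years Chronological age(s) in years, non-negative.
#' @param max_lifespan_years Species maximum lifespan in years, positive.
#' @return `age_years / max_lifespan_years`, a numeric vector.
#' @examples
#' relative_age(15.15, 30.3) # 0.5
#' @export
relative_age <- function(age_years, max_lifespan_years) {
  assert_scalar_number(max_lifespan_years, "max_lifespan_years")
  if (max_lifespan_years <= 0) {
    stop_domain("`max_lifespan_years` must be positive")
  }
  if (any(age_years < 0, na.rm = TRUE)) {
    stop_domain("`age_years` must be non-negative")
  }
  out <- age_years / max_lifespan_years
  if (any(out > 1, na.rm = TRUE)) {
    warn("relative age exceeds 1: age above the registry maximum lifespan")
  }
  out
}

#' Log-linear age transformation
#'
#' A monotone map of chronological age used as the regression response for
#' multi-species chronological clocks. It is logarithmic before the species'
#' age at sexual maturity `m` and linear after, which normalizes the "speed"
#' of the clock with respect to maturity while preserving resolution at
#' embryonic and larval ages:
#' \deqn{F(a) = \log\frac{a + k}{m + k} \ (a \le m), \qquad
#'       F(a) = \frac{a - m}{m + k} \ (a > m).}
#' The two pieces meet at `F(m) = 0` with equal one-sided derivatives
#' `1/(m+k)`, so `F` is continuously differentiable, strictly increasing, and
#' invertible. The offset `k` (default `m/5`) keeps age 0 finite and tunes
#' how much resolution the log region devotes to early life.
#'
#' @param age_years Chronological age(s) in years, non-negative.
#' @param maturity_years Age at sexual maturity `m` in years, positive.
#' @param offset_years Offset `k` in years, positive; default `maturity_years/5`.
#' @return Transformed age (dimensionless), same length as `age_years`.
#' @seealso [loglinear_inverse()]
#' @export
loglinear_forward <- function(age_years, maturity_years,
                              offset_years = maturity_years / 5) {
  check_loglinear_params(maturity_years, offset_years)
  if (any(age_years < 0, na.rm = TRUE)) {
    stop_domain("`age_years` must be non-negative")
  }
  m <- maturity_years
  k <- offset_years
  ifelse(age_years <= m,
         log((age_years + k) / (m + k)),
         (age_years - m) / (m + k))
}

#' Inverse log-linear age transformation
#'
#' Exact inverse of [loglinear_forward()], used to report clock predictions in
#' units of years. Transformed values below `F(0) = log(k/(m+k))` correspond
#' to ages before birth/fertilization; they are inverted anyway (yielding a
#' negative age) with a warning, so that downstream code can decide how to
#' display such extrapolations.
#'
#' @inheritParams loglinear_forward
#' @param y Transformed age(s), any real number.
#' @return Age(s) in years.
#' @export
loglinear_inverse <- function(y, maturity_years,
                              offset_years = maturity_years / 5) {
  check_loglinear_params(maturity_years, offset_years)
  m <- maturity_years
  k <- offset_years
  floor_y <- log(k / (m + k))
  if (any(y < floor_y, na.rm = TRUE)) {
    warn("transformed age below F(0): below-birth extrapolation, age < 0")
  }
  ifelse(y <= 0, (m + k) * exp(y) - k, m + y * (m + k))
}

check_loglinear_params <- function(m, k) {
  assert_scalar_number(m, "maturity_years")
  assert_scalar_number(k, "offset_years")
  if (m <= 0 || k <= 0) {
    stop_domain("maturity_years and offset_years must be positive")
  }
  invisible(TRUE)
}

#' Species-aware age transform specification
#'
#' Bundles a transform kind with per-species parameters drawn from a species
#' registry, so that a fitted clock is self-describing: the same object maps
#' ages to the regression response at training time and maps linear-predictor
#' scores back to ages (or relative ages) at prediction time.
#'
#' Kinds:
#' * `identity` — response is chronological age in years (used by the
#'   single-species clocks);
#' * `loglinear` — response is [loglinear_forward()] with each sample's
#'   species maturity (pan-tissue and dual-species chronological clocks);
#' * `relative` — response is [relative_age()] with each sample's species
#'   maximum lifespan (relative-age clocks; predictions stay on the relative
#'   scale and are species-free).
#'
#' @param kind One of `"identity"`, `"loglinear"`, `"relative"`.
#' @param registry A species registry (see [default_species_registry()]).
#' @param offset_ratio For `loglinear`: the offset `k` as a fraction of
#'   maturity `m` (default 0.2, i.e. `k = m/5`).
#' @return An object of class `age_transform`.
#' @export
age_transform <- function(kind = c("identity", "loglinear", "relative"),
                          registry = default_species_registry(),
                          offset_ratio = 0.2) {
  kind <- match.arg(kind)
  registry <- validate_species_registry(registry)
  params <- tibble::tibble(
    species = registry$species,
    maturity_years = registry$maturity_years,
    offset_years = registry$maturity_years * offset_ratio,
    max_lifespan_years = registry$max_lifespan_years
  )
  structure(list(kind = kind, params = params), class = "age_transform")
}

#' @export
print.age_transform <- function(x, ...) {
  cat("<age_transform> kind:", x$kind, "\n")
  print(x$params)
  invisible(x)
}

transform_params <- function(spec, species) {
  i <- match(species, spec$params$species)
  if (anyNA(i)) {
    stop_validation(paste0(
      "species not covered by age transform: ",
      toString(unique(species[is.na(i)]))
    ))
  }
  spec$params[i, ]
}

#' Apply / invert an age transform per sample species
#'
#' @param spec An [age_transform()] object.
#' @param age_years Ages in years (for `transform_age`).
#' @param y Response-scale values (for `untransform_age`).
#' @param species Character vector of species labels, recycled against ages.
#' @return Numeric vector on the response scale (`transform_age`) or the
#'   reporting scale — years, or lifespan fractions for `relative`
#'   (`untransform_age`).
#' @export
transform_age <- function(spec, age_years, species) {
  switch(spec$kind,
    identity = as.numeric(age_years),
    loglinear = {
      p <- transform_params(spec, species)
      m <- p$maturity_years
      k <- p$offset_years
      ifelse(age_years <= m,
             log((age_years + k) / (m + k)),
             (age_years - m) / (m + k))
    },
    relative = {
      p <- transform_params(spec, species)
      age_years / p$max_lifespan_years
    }
  )
}

#' @rdname transform_age
#' @export
untransform_age <- function(spec, y, species) {
  switch(spec$kind,
    identity = as.numeric(y),
    loglinear = {
      p <- transform_params(spec, species)
      m <- p$maturity_years
      k <- p$offset_years
      ifelse(y <= 0, (m + k) * exp(y) - k, m + y * (m + k))
    },
    # relative clocks report lifespan fractions directly
    relative = as.numeric(y)
  )
}

#' Observed response for a set of samples under a transform
#'
#' The scale on which cross-validated predictions are compared to truth:
#' years for `identity` and `loglinear` clocks (predictions are
#' back-transformed), lifespan fractions for `relative` clocks.
#' @keywords internal
observed_on_report_scale <- function(spec, age_years, species) {
  if (spec$kind == "relative") {
    p <- transform_params(spec, species)
    age_years / p$max_lifespan_years
  } else {
    as.numeric(age_years)
  }
}
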