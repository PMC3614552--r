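## Linear solubility models sol = c1*desc + c2*q + c3 (the developability-
## index family: net charge plus one additional descriptor), the coefficient
## ratio used to compare models across data sets, and extraction of the
## contact minimum from potential-of-mean-force curves.

#' Construct a linear solubility model object
#'
#' Mostly produced by [fit_lr()]; the constructor is exported so published
#' coefficient sets can be wrapped and fed to [coefficient_ratio()].
#'
#' @param descriptor descriptor name ("p", "nsap", "sapmax", ...).
#' @param c1 coefficient on the descriptor.
#' @param c2 coefficient on the net charge q.
#' @param c3 intercept.
#' @param r2 squared correlation between fit and observation (optional).
#' @param p_value overall F-test probability (optional).
#' @param n_obs number of observations (optional).
#' @return an object of class `lr_model`.
#' @export
lr_model <- function(descriptor, c1, c2, c3, r2 = NA_real_,
                     p_value = NA_real_, n_obs = NA_integer_) {
  structure(list(descriptor = descriptor, c1 = c1, c2 = c2, c3 = c3,
                 r2 = r2, p_value = p_value, n_obs = n_obs),
            class = "lr_model")
}

#' @export
print.lr_model <- function(x, ...) {
  cat(sprintf("linear solubility model: sol = %.4g*%s %+.4g*q %+.4g\n",
              x$c1, x$descriptor, x$c2, x$c3))
  if (is.finite(x$r2))
    cat(sprintf("  r^2 = %.3f, P = %.3g (F-test), n = %d\n",
                x$r2, x$p_value, x$n_obs))
  invisible(x)
}

#' Fit the linear solubility model sol = c1*desc + c2*q + c3
#'
#' Ordinary least squares of the observed solubility on one descriptor and
#' the net charge.  `r2` is the coefficient of determination and `p_value`
#' the overall F-test of the full model against the intercept-only model
#' with (2, n - 3) degrees of freedom.
#'
#' @param desc descriptor vector (dipole moment, nSAP or SAPmax).
#' @param q net-charge vector, e.
#' @param sol observed solubility vector.
#' @param descriptor descriptor name stored in the model.
#' @return an `lr_model`.
#' @export
fit_lr <- function(desc, q, sol, descriptor = "desc") {
  n <- length(sol)
  if (length(desc) != n || length(q) != n)
    stop("desc, q and sol must have equal length")
  if (n < 4) stop("need at least 4 observations to fit 3 parameters")
  if (!all(is.finite(desc), is.finite(q), is.finite(sol)))
    stop("inputs must be finite")
  X <- cbind(1, desc, q)
  if (qr(X)$rank < 3 ||
      abs(stats::cor(desc, q)) > 1 - 1e-10)
    stop("design is rank deficient (descriptor collinear with q)")
  fit <- stats::lm(sol ~ desc + q)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  lr_model(descriptor = descriptor,
           c1 = unname(stats::coef(fit)["desc"]),
           c2 = unname(stats::coef(fit)["q"]),
           c3 = unname(stats::coef(fit)["(Intercept)"]),
           r2 = sm$r.squared,
           p_value = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                                      lower.tail = FALSE)),
           n_obs = n)
}

#' Coefficient ratio c2/c1 of a solubility model
#'
#' When only relative solubilities matter the two-predictor model collapses
#' to a single number: the ratio of the net-charge coefficient to the
#' descriptor coefficient.  Similar ratios across very different data sets
#' indicate that the same pair of properties dominates relative solubility.
#'
#' @param m an `lr_model` (or list with elements `c1`, `c2`).
#' @return `c2 / c1`.
#' @export
coefficient_ratio <- function(m) {
  if (!all(c("c1", "c2") %in% names(m)))
    stop("need a model with coefficients c1 and c2")
  if (m$c1 == 0) stop("descriptor coefficient c1 is zero; ratio undefined")
  m$c2 / m$c1
}

#' Pearson correlation with defined-input guards
#'
#' @param x,y equal-length numeric vectors (length >= 3, both non-constant).
#' @return sample Pearson correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant vector")
  stats::cor(x, y)
}

#' Construct a PMF curve
#'
#' @param separations strictly increasing separations, Angstrom (>= 5
#'   points).
#' @param free_energy free energies, kJ/mol.
#' @param error optional per-point error bars, kJ/mol.
#' @return an object of class `pmf_curve`.
#' @export
pmf_curve <- function(separations, free_energy, error = NULL) {
  if (length(separations) != length(free_energy))
    stop("separations and free_energy must have equal length")
  if (length(separations) < 5) stop("a PMF curve needs at least 5 points")
  if (any(diff(separations) <= 0))
    stop("separations must be strictly increasing")
  if (!all(is.finite(separations), is.finite(free_energy)))
    stop("values must be finite")
  structure(list(separations = as.numeric(separations),
                 free_energy = as.numeric(free_energy),
                 error = if (is.null(error)) NULL else as.numeric(error)),
            class = "pmf_curve")
}

#' Contact minimum of a PMF curve
#'
#' Finds the local minimum closest to contact (smallest separation): the
#' first interior point strictly lower than both neighbours.  If there is no
#' interior minimum, the contact endpoint is accepted as a bound minimum
#' only when the curve rises away from it into a negative well
#' (`fe[1] < fe[2]` and `fe[1] < 0`); a curve that is repulsive at contact
#' and decays monotonically outward -- or rises monotonically from a
#' non-negative contact value -- has no bound minimum.
#'
#' @param c a `pmf_curve`.
#' @return list with `bound` (logical), `separation` (Angstrom) and
#'   `dg_min` (kJ/mol); the latter two are `NA` when `bound` is FALSE.
#' @export
contact_minimum <- function(c) {
  stopifnot(inherits(c, "pmf_curve"))
  fe <- c$free_energy
  r <- c$separations
  n <- length(fe)
  for (i in 2:(n - 1)) {
    if (fe[i] < fe[i - 1] && fe[i] < fe[i + 1])
      return(list(bound = TRUE, separation = r[i], dg_min = fe[i]))
  }
  if (fe[1] < fe[2] && fe[1] < 0)
    return(list(bound = TRUE, separation = r[1], dg_min = fe[1]))
  list(bound = FALSE, separation = NA_real_, dg_min = NA_real_)
}

#' Read / write tabulated PMF curves
#'
#' Two- or three-column whitespace-separated text: separation (Angstrom),
#' free energy (kJ/mol) and optional error bar (kJ/mol).  Lines starting
#' with `#` are comments.
#'
#' @param path input file.
#' @return a `pmf_curve`.
#' @export
read_pmf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, comment.char = "#")
  if (ncol(tab) < 2) stop("PMF file needs at least two columns")
  pmf_curve(tab[[1]], tab[[2]],
            error = if (ncol(tab) >= 3) tab[[3]] else NULL)
}

#' @rdname read_pmf
#' @param c a `pmf_curve` to write.
#' @export
write_pmf <- function(c, path) {
  stopifnot(inherits(c, "pmf_curve"))
  cols <- cbind(c$separations, c$free_energy)
  if (!is.null(c$error)) cols <- cbind(cols, c$error)
  utils::write.table(format(cols, digits = 10, trim = TRUE), path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
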