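# Model parameters. The baseline set is this package's own calibration that
# reproduces the qualitative wild-type patterning sequence (distal convergence
# at the source, CUC-band repolarization, emergent proximal convergence and
# auxin maximum); it is versioned here and is not a published parameter table.

#' Model parameters for the PIN-auxin dynamics
#'
#' Collects every kinetic, allocation and numerical parameter of the model.
#' An explicit-scheme stability guard is checked at construction:
#' `dt * (mu_a + 4 D + 4 T P_tot max(1, epsilon)) < 1`.
#'
#' @param variant Model variant: `"pmm"` (CUC-induced PIN phosphorylation
#'   switches the polarization rule from up-the-gradient to with-the-flux),
#'   `"emm"` (phosphorylated PIN transports with efficiency `epsilon`), or
#'   `"utg_only"` (control without any CUC effect on PIN).
#' @param sigma_src Auxin production rate at source cells (a.u. / t).
#' @param sigma_bg Background auxin production in every cell (a.u. / t).
#' @param mu_a First-order auxin decay rate (1 / t).
#' @param D Passive diffusion coefficient between neighbor cells (1 / t).
#' @param T_rate PIN-mediated transport rate per PIN unit (1 / t).
#' @param P_tot Total PIN per cell (PIN units); allocation over membranes
#'   always sums to this.
#' @param kappa Up-the-gradient sensitivity: the exponent of the `"power"`
#'   response (dimensionless) or the softmax gain (1 / a.u.); see
#'   [utg_weights()].
#' @param utg_form Up-the-gradient response form, `"power"` (baseline:
#'   relative, scale-invariant sensing) or `"softmax"` (absolute sensing).
#' @param wtf_exponent Flux-response exponent of the with-the-flux weighting.
#' @param beta Baseline membrane affinity in the with-the-flux weighting
#'   (> 0; prevents 0/0 when all fluxes are inward).
#' @param K_c CUC half-saturation of PIN phosphorylation (a.u.).
#' @param h_c Hill coefficient of phosphorylation (>= 1).
#' @param epsilon Transport-efficiency multiplier of phosphorylated PIN
#'   (>= 1; only acts under the EMM).
#' @param rho PIN reallocation relaxation rate toward targets (1 / t).
#' @param dt Integration time step (t).
#' @param tol_ss Steady-state tolerance on max |da/dt| (a.u. / t).
#' @param t_max Integration horizon (t).
#' @return A `margin_params` object (named list).
#' @examples
#' p <- margin_params("pmm")
#' p
#' @export
margin_params <- function(variant = c("pmm", "emm", "utg_only"),
                          sigma_src = 1, sigma_bg = 0, mu_a = 0.02,
                          D = 0.25, T_rate = 0.55, P_tot = 1,
                          kappa = 2, utg_form = c("power", "softmax"),
                          wtf_exponent = 2, beta = 1e-6,
                          K_c = 1, h_c = 2, epsilon = 3,
                          rho = 0.2, dt = 0.1, tol_ss = 1e-6, t_max = 1500) {
  variant <- match.arg(variant)
  utg_form <- match.arg(utg_form)
  p <- list(variant = variant, utg_form = utg_form, sigma_src = sigma_src, sigma_bg = sigma_bg,
            mu_a = mu_a, D = D, T_rate = T_rate, P_tot = P_tot,
            kappa = kappa, wtf_exponent = wtf_exponent, beta = beta,
            K_c = K_c, h_c = h_c, epsilon = epsilon, rho = rho,
            dt = dt, tol_ss = tol_ss, t_max = t_max)
  rates <- c("sigma_src", "sigma_bg", "mu_a", "D", "T_rate", "P_tot",
             "kappa", "wtf_exponent", "rho", "dt", "tol_ss", "t_max")
  for (nm in rates)
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] < 0)
      stop(nm, " must be a single non-negative number")
  if (beta <= 0) stop("beta must be > 0 (prevents degenerate 0/0 weights)")
  if (K_c <= 0) stop("K_c must be > 0")
  if (h_c < 1) stop("h_c must be >= 1")
  if (epsilon < 1) stop("epsilon must be >= 1")
  guard <- dt * (mu_a + 4 * D + 4 * T_rate * P_tot * max(1, epsilon))
  if (guard >= 1)
    stop("explicit-scheme stability guard violated: dt*(mu_a + 4D + ",
         "4*T*P_tot*max(1,epsilon)) = ", format(guard),
         " must be < 1; reduce dt")
  structure(p, class = "margin_params")
}

#' @export
print.margin_params <- function(x, ...) {
  cat("PIN-auxin model parameters (variant: ", x$variant, ")\n", sep = "")
  nm <- setdiff(names(x), "variant")
  vals <- vapply(nm, function(k) format(x[[k]]), "")
  cat(paste0("  ", format(nm, width = 12), " = ", vals), sep = "\n")
  invisible(x)
}

#' Write / read model parameters as a structured text config
#'
#' @param params A `margin_params` object.
#' @param path File path.
#' @return `read_params` returns a `margin_params`; `write_params` returns
#'   `path` invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "margin_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(margin_params, cfg)
}
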