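#' Construct a model parameter object
#'
#' Assembles geometry, phenomenological coefficients, ATP kinetics and the
#' initial state into a validated `ion_params` object. The coefficient matrix
#' couples the four ion fluxes (H+, K+, Na+, Cl-) and the ATP hydrolysis
#' reaction; Onsager reciprocity is structural (only one triangle is stored).
#' Four coefficients are glucose-modifiable (`HH`, `KK`, `HAr`, `KAr`): after
#' the glucose event each relaxes from its initial value towards its
#' post-glucose asymptote `aG` with rate constant `k_decr = k_incr / aG`.
#'
#' @param geometry an [cell_geometry()] object (or list with the same fields).
#' @param L named list of static coefficients, mol^2/(J m^2 s). Recognised
#'   names: `HK`, `HNa`, `HCl`, `KNa`, `KCl`, `NaCl`, `NaNa`, `ClCl`.
#'   Unlisted entries are 0. Diagonal entries must be non-negative.
#' @param dynamic named list for the glucose-modifiable coefficients `HH`,
#'   `KK`, `HAr`, `KAr`; each element a list with `init` (value before
#'   glucose), `aG` (post-glucose asymptote) and `k_incr` (increase rate,
#'   mol^2/(J m^2 s^2)). `k_incr = 0` marks the coefficient static at `init`.
#'   `HAr`/`KAr` start at 0 (no active transport in starved cells).
#' @param atp list with `C_ATP` (equilibrium ATP concentration, mM), `K`
#'   (reaction equilibrium constant), `ATP_stimulus` (post-glucose ATP
#'   asymptote, mM), `k_ATPincr` (mol m-3 s-1) and `ATP0` (initial ATP, mM).
#' @param init named list of initial conditions: `H_out`, `K_out`, `Na_out`,
#'   `Cl_out`, `K_in`, `Na_in`, `Cl_in` (mM), `pH_in`, and `delta_phi` (V,
#'   inside minus outside).
#' @param variant `"M1"` (ATP-driven K+ import allowed) or `"M2"`
#'   (`L_KAr` fixed at 0).
#' @param name optional label.
#' @return An object of class `ion_params`.
#' @seealso [parameter_set()] for the published sets P1, P2a, P2b.
#' @export
ion_params <- function(geometry = cell_geometry(),
                       L = list(),
                       dynamic = list(),
                       atp = list(C_ATP = 0.3, K = 0, ATP_stimulus = 2.5,
                                  k_ATPincr = 0, ATP0 = 2.5),
                       init = list(),
                       variant = c("M2", "M1"),
                       name = "custom") {
  variant <- match.arg(variant)
  if (!inherits(geometry, "ion_geometry")) {
    geometry <- do.call(cell_geometry, geometry)
  }

  L_names <- c("HK", "HNa", "HCl", "KNa", "KCl", "NaCl", "NaNa", "ClCl")
  Ls <- stats::setNames(as.list(rep(0, length(L_names))), L_names)
  unknown <- setdiff(names(L), L_names)
  if (length(unknown))
    stop("unknown static coefficient(s): ", paste(unknown, collapse = ", "))
  Ls[names(L)] <- L

  dyn_names <- c("HH", "KK", "HAr", "KAr")
  dyn <- stats::setNames(vector("list", 4), dyn_names)
  for (nm in dyn_names) {
    d <- dynamic[[nm]]
    if (is.null(d)) d <- list()
    init_default <- if (nm %in% c("HAr", "KAr")) 0 else 0
    d <- list(init   = if (is.null(d$init)) init_default else d$init,
              aG     = if (is.null(d$aG)) 0 else d$aG,
              k_incr = if (is.null(d$k_incr)) 0 else d$k_incr)
    d$k_decr <- if (d$k_incr == 0) 0 else {
      if (d$aG == 0) stop("dynamic coefficient ", nm,
                          ": aG must be nonzero when k_incr is nonzero")
      d$k_incr / d$aG
    }
    dyn[[nm]] <- d
  }
  unknown <- setdiff(names(dynamic), dyn_names)
  if (length(unknown))
    stop("unknown dynamic coefficient(s): ", paste(unknown, collapse = ", "))

  if (variant == "M2" &&
      (dyn$KAr$init != 0 || dyn$KAr$k_incr != 0 || dyn$KAr$aG != 0))
    stop("variant M2 requires L_KAr = 0 (no ATP-driven K+ import)")

  # straight coefficients must be non-negative
  bad <- character()
  if (Ls$NaNa < 0) bad <- c(bad, "L_NaNa")
  if (Ls$ClCl < 0) bad <- c(bad, "L_ClCl")
  if (dyn$HH$init < 0) bad <- c(bad, "L_HHinit")
  if (dyn$KK$init < 0) bad <- c(bad, "L_KKinit")
  if (length(bad))
    stop("negative straight coefficient(s): ", paste(bad, collapse = ", "))

  atp_defaults <- list(C_ATP = 0.3, K = 0, ATP_stimulus = 2.5,
                       k_ATPincr = 0, ATP0 = 2.5)
  atp_defaults[names(atp)] <- atp
  atp <- lapply(atp_defaults, as.numeric)
  if (atp$C_ATP <= 0) stop("equilibrium ATP concentration C_ATP must be > 0")
  if (atp$ATP_stimulus <= 0) stop("ATP_stimulus must be > 0")
  atp$k_ATPdecr <- atp$k_ATPincr / atp$ATP_stimulus

  init_defaults <- list(H_out = ph_to_mM(5.5, geometry$cf), K_out = 0.1,
                        Na_out = 0.01, Cl_out = 0.1, pH_in = 6.5,
                        K_in = 75, Na_in = 15, Cl_in = 0.5,
                        delta_phi = -0.15)
  unknown <- setdiff(names(init), names(init_defaults))
  if (length(unknown))
    stop("unknown initial condition(s): ", paste(unknown, collapse = ", "))
  init_defaults[names(init)] <- init
  init <- init_defaults
  init$H_in <- ph_to_mM(init$pH_in, geometry$cf)
  conc <- unlist(init[c("H_in", "K_in", "Na_in", "Cl_in",
                        "H_out", "K_out", "Na_out", "Cl_out")])
  if (any(conc <= 0))
    stop("non-positive initial concentration(s): ",
         paste(names(conc)[conc <= 0], collapse = ", "))

  obj <- list(geometry = geometry, L = Ls, dynamic = dyn, atp = atp,
              init = init, variant = variant, name = name,
              Bf = buffering_factor(geometry$pbc, init$H_in))
  class(obj) <- "ion_params"
  obj
}

#' Load a published or user-supplied parameter set
#'
#' Loads one of the shipped parameter sets (`"P1"`, `"P2a"`, `"P2b"`) or a
#' YAML file in the same layout, validates it, and reports the derived
#' quantities (`k_ATPdecr`, per-coefficient `k_decr`, buffering factor `Bf`).
#' P1 is the model variant M1 (with an ATP-driven K+ import coefficient);
#' P2a and P2b are variant M2 fits.
#'
#' @param name_or_path `"P1"`, `"P2a"`, `"P2b"`, or path to a YAML file.
#' @param Cm specific membrane capacitance, F m-2 (not part of the published
#'   tables; see [cell_geometry()]).
#' @return An `ion_params` object.
#' @export
#' @examples
#' p <- parameter_set("P2a")
#' p$L$ClCl          # 3.08e-7 mol^2/(J m^2 s)
#' p$init$delta_phi  # -0.168 V
parameter_set <- function(name_or_path, Cm = 0.01) {
  if (name_or_path %in% c("P1", "P2a", "P2b")) {
    path <- system.file("extdata", "parameter_sets",
                        paste0(name_or_path, ".yaml"), package = "ionNET")
  } else {
    path <- name_or_path
  }
  if (!nzchar(path) || !file.exists(path))
    stop("parameter set not found: ", name_or_path)
  cfg <- yaml::read_yaml(path)
  for (section in c("global", "initial", "coefficients"))
    if (is.null(cfg[[section]]))
      stop("parameter file ", path, " lacks section '", section, "'")
  # YAML scalars like "3e-7" (no decimal point) arrive as strings
  as_num <- function(section) lapply(section, function(x) {
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v)) stop("non-numeric value in ", path, ": ", x)
    v
  })
  g <- as_num(cfg$global); ic <- as_num(cfg$initial)
  co <- as_num(cfg$coefficients)

  known <- c("L_HHinit", "L_HHaG", "L_KK", "L_KKinit", "L_KKaG", "L_KAraG",
             "L_HK", "L_HNa", "L_HCl", "L_KNa", "L_KCl", "L_NaCl",
             "L_NaNa", "L_ClCl", "L_HAraG",
             "k_incrHH", "k_incrKK", "k_incrHAr", "k_incrKAr", "k_ATPincr")
  unknown <- setdiff(names(co), known)
  if (length(unknown))
    stop("unknown coefficient key(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  if (!is.null(co$L_KK) && !is.null(co$L_KKinit))
    stop("give either L_KK (static) or L_KKinit/L_KKaG (dynamic), not both")

  val <- function(x, default = 0) if (is.null(x)) default else x
  geometry <- cell_geometry(
    V_out = g$V_out, temperature = g$T, Cm = Cm,
    pbc = g$pbc, cf = val(g$cf, 1000))
  # honour printed Surf/V_in exactly if they differ from the cell-count product
  geometry$Surf <- val(g$Surf, geometry$Surf)
  geometry$V_in <- val(g$V_in, geometry$V_in)

  dynamic <- list(
    HH  = list(init = val(co$L_HHinit), aG = val(co$L_HHaG),
               k_incr = val(co$k_incrHH)),
    KK  = if (is.null(co$L_KKinit))
            list(init = val(co$L_KK), aG = 0, k_incr = 0)
          else
            list(init = co$L_KKinit, aG = val(co$L_KKaG),
                 k_incr = val(co$k_incrKK)),
    HAr = list(init = 0, aG = val(co$L_HAraG), k_incr = val(co$k_incrHAr)),
    KAr = list(init = 0, aG = val(co$L_KAraG), k_incr = val(co$k_incrKAr)))

  ion_params(
    geometry = geometry,
    L = list(HK = val(co$L_HK), HNa = val(co$L_HNa), HCl = val(co$L_HCl),
             KNa = val(co$L_KNa), KCl = val(co$L_KCl), NaCl = val(co$L_NaCl),
             NaNa = val(co$L_NaNa), ClCl = val(co$L_ClCl)),
    dynamic = dynamic,
    atp = list(C_ATP = g$C_ATP, K = g$K, ATP_stimulus = ic$ATP_stimulus,
               k_ATPincr = val(co$k_ATPincr), ATP0 = ic$ATP),
    init = list(H_out = ic$H_out, K_out = ic$K_out, Na_out = ic$Na_out,
                Cl_out = ic$Cl_out, pH_in = ic$pH_in, K_in = ic$K_in,
                Na_in = ic$Na_in, Cl_in = ic$Cl_in,
                delta_phi = g$delta_phi),
    variant = val(cfg$variant, "M2"),
    name = val(cfg$name, basename(path)))
}

#' @export
print.ion_params <- function(x, ...) {
  cat(sprintf("Ion-transport parameter set '%s' (variant %s)\n",
              x$name, x$variant))
  cat(sprintf("  delta_phi0 %+.4g V | ATP0 %.4g mM -> plateau %.4g mM (k_ATPdecr %.4g /s)\n",
              x$init$delta_phi, x$atp$ATP0, x$atp$ATP_stimulus, x$atp$k_ATPdecr))
  cat(sprintf("  Bf %.4g (pbc %g mM/pH at pH_in %.4g)\n",
              x$Bf, x$geometry$pbc, x$init$pH_in))
  dyn <- x$dynamic
  for (nm in names(dyn)) {
    d <- dyn[[nm]]
    if (d$k_incr != 0)
      cat(sprintf("  L_%s dynamic: %.3g -> %.3g (k_incr %.3g, k_decr %.3g)\n",
                  nm, d$init, d$aG, d$k_incr, d$k_decr))
  }
  stat <- unlist(x$L)
  stat <- stat[stat != 0]
  if (length(stat))
    cat("  static L:", paste(sprintf("%s=%.3g", names(stat), stat),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Assemble the 5x5 phenomenological coefficient matrix
#'
#' Builds the symmetric matrix over the flux indices (H, K, Na, Cl, Ar) from
#' an `ion_params` object and the live values of the glucose-modifiable
#' coefficients. Reciprocity holds by construction. `L_NaAr`, `L_ClAr` and
#' `L_ArAr` are structurally 0 (no Na+/ATP coupling; the reaction's straight
#' coefficient is not part of the published model).
#'
#' @param params an `ion_params` object.
#' @param live optional named numeric with current values for `HH`, `KK`,
#'   `HAr`, `KAr`; defaults to their initial values.
#' @return 5x5 symmetric numeric matrix, dimnames `c("H","K","Na","Cl","Ar")`.
#' @export
coefficient_matrix <- function(params, live = NULL) {
  d <- params$dynamic
  v <- c(HH = d$HH$init, KK = d$KK$init, HAr = d$HAr$init, KAr = d$KAr$init)
  if (!is.null(live)) v[names(live)] <- live
  s <- params$L
  ions <- c("H", "K", "Na", "Cl", "Ar")
  m <- matrix(0, 5, 5, dimnames = list(ions, ions))
  m["H", "H"] <- v[["HH"]]; m["K", "K"] <- v[["KK"]]
  m["Na", "Na"] <- s$NaNa;  m["Cl", "Cl"] <- s$ClCl
  m["H", "K"] <- m["K", "H"] <- s$HK
  m["H", "Na"] <- m["Na", "H"] <- s$HNa
  m["H", "Cl"] <- m["Cl", "H"] <- s$HCl
  m["K", "Na"] <- m["Na", "K"] <- s$KNa
  m["K", "Cl"] <- m["Cl", "K"] <- s$KCl
  m["Na", "Cl"] <- m["Cl", "Na"] <- s$NaCl
  m["H", "Ar"] <- m["Ar", "H"] <- v[["HAr"]]
  m["K", "Ar"] <- m["Ar", "K"] <- v[["KAr"]]
  m
}

#' Check thermodynamic admissibility of a coefficient matrix
#'
#' Verifies the conditions a phenomenological coefficient matrix must satisfy:
#' non-negative straight coefficients (hard), symmetry (hard — structural when
#' built by [coefficient_matrix()]), and positive-semidefiniteness /
#' non-negative determinant (warning-level: the published fits leave the
#' reaction's straight coefficient at 0, so their full matrices sit outside
#' the PSD cone whenever an ATP cross-coupling is active).
#'
#' @param L numeric square symmetric matrix (e.g. from
#'   [coefficient_matrix()]), or an `ion_params` object.
#' @param tol numerical tolerance for symmetry/eigenvalue checks.
#' @return A list of class `onsager_report` with logical fields
#'   `diagonal_ok`, `symmetric`, `psd`, `det_ok`, the offending entries, and
#'   an overall `hard_ok`.
#' @export
validate_onsager <- function(L, tol = 1e-12) {
  if (inherits(L, "ion_params")) L <- coefficient_matrix(L)
  stopifnot(is.matrix(L), nrow(L) == ncol(L))
  dn <- rownames(L)
  if (is.null(dn)) dn <- as.character(seq_len(nrow(L)))
  diag_bad <- dn[diag(L) < 0]
  sym <- max(abs(L - t(L))) <= tol * max(1, max(abs(L)))
  ev <- eigen((L + t(L)) / 2, symmetric = TRUE, only.values = TRUE)$values
  scale <- max(abs(ev), 1e-300)
  psd <- all(ev >= -tol * scale)
  det_ok <- det(L) >= -tol * scale^nrow(L)
  rep <- list(diagonal_ok = length(diag_bad) == 0,
              negative_diagonal = diag_bad,
              symmetric = sym,
              psd = psd,
              det_ok = det_ok,
              eigenvalues = ev,
              hard_ok = length(diag_bad) == 0 && sym)
  class(rep) <- "onsager_report"
  rep
}

#' @export
print.onsager_report <- function(x, ...) {
  cat("Onsager admissibility report\n")
  cat(sprintf("  straight coefficients >= 0 : %s%s\n",
              if (x$diagonal_ok) "ok" else "VIOLATION",
              if (length(x$negative_diagonal))
                paste0(" (", paste(x$negative_diagonal, collapse = ", "), ")")
              else ""))
  cat(sprintf("  symmetry (reciprocity)     : %s\n",
              if (x$symmetric) "ok" else "VIOLATION"))
  cat(sprintf("  PSD / det >= 0             : %s (warning-level)\n",
              if (x$psd) "ok" else "not satisfied"))
  invisible(x)
}
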