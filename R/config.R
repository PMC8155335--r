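# YAML run configuration: forcefield / system / protocol / analysis
# blocks with validated defaults.

config_defaults <- function() {
  list(
    forcefield = list(solvent_condition = "good", cutoff = 1,
                      bond_k = 128, bond_l0 = 0.5, bend_k = 20,
                      gamma = 4.5),
    system = list(builder = "bulk_water", box = c(10, 10, 10),
                  Phi_S = 0, rho = 3),
    protocol = list(ensemble = "NVT", dt = 0.01, lambda = 0.65,
                    n_steps = 1000L, frame_stride = 0L,
                    obs_stride = 100L, p_target = 23.7, tau_p = 10,
                    seed = NULL),
    analysis = list(bin_width = 0.25, stress_bin_width = 0.2)
  )
}

#' Load and validate a YAML run configuration
#'
#' Reads the \code{forcefield:}, \code{system:}, \code{protocol:} and
#' \code{analysis:} blocks, fills documented defaults for absent keys,
#' and validates types and ranges. A \code{protocol: seed} is mandatory:
#' every source of randomness in a run flows from it.
#'
#' @param path Path to a YAML file.
#' @return A validated config list of class \code{run_config}, with
#'   \code{$forcefield_obj} holding the constructed
#'   \code{dpd_forcefield} and \code{$config_hash} a digest of the
#'   normalised config.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  cfg <- config_defaults()
  for (block in names(cfg)) {
    if (!is.null(raw[[block]])) {
      unknown <- setdiff(names(raw[[block]]), c(names(cfg[[block]]), "f"))
      if (length(unknown))
        stop("config block `", block, "` has unknown key(s): ",
             paste(unknown, collapse = ", "))
      cfg[[block]] <- utils::modifyList(cfg[[block]], raw[[block]])
    }
  }
  p <- cfg$protocol
  if (is.null(p$seed)) stop("config key `protocol: seed` is mandatory")
  if (!is.numeric(p$dt) || p$dt <= 0)
    stop("config key `protocol: dt` must be a positive number")
  if (!p$ensemble %in% c("NVT", "NPT"))
    stop("config key `protocol: ensemble` must be NVT or NPT")
  if (p$lambda <= 0 || p$lambda >= 1)
    stop("config key `protocol: lambda` must be in (0, 1)")
  s <- cfg$system
  if (!is.null(s$Phi_S) && (s$Phi_S < 0 || s$Phi_S > 1))
    stop("config key `system: Phi_S` must be in [0, 1]")
  fblock <- cfg$forcefield
  if (!fblock$solvent_condition %in% c("good", "poor"))
    stop("config key `forcefield: solvent_condition` must be good or poor")
  if (!is.null(raw$forcefield$f)) {
    f <- matrix(unlist(raw$forcefield$f), 4, 4, byrow = TRUE,
                dimnames = list(bead_types(), bead_types()))
    ff <- dpd_forcefield(f, cutoff = fblock$cutoff, bond_k = fblock$bond_k,
                         bond_l0 = fblock$bond_l0, bend_k = fblock$bend_k,
                         gamma = fblock$gamma)
  } else {
    ff <- default_force_table(fblock$solvent_condition,
                              cutoff = fblock$cutoff,
                              bond_k = fblock$bond_k,
                              bond_l0 = fblock$bond_l0,
                              bend_k = fblock$bend_k,
                              gamma = fblock$gamma)
  }
  cfg$forcefield_obj <- ff
  norm <- cfg[c("forcefield", "system", "protocol", "analysis")]
  cfg$config_hash <- substr(config_digest(norm), 1, 12)
  structure(cfg, class = "run_config")
}

# order-stable polynomial rolling digest of the deparse of a list
config_digest <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x%04x", as.integer(h), nchar(s) %% 65536)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("Run config [%s]: %s builder, %s ensemble, %d steps, seed %s\n",
              x$config_hash, x$system$builder, x$protocol$ensemble,
              as.integer(x$protocol$n_steps),
              as.character(x$protocol$seed)))
  invisible(x)
}
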