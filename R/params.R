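# Bond detection parameters: one sub-record per bond type, every value a
# user-facing knob (the original defaults of the method's supplementary
# tables are not fixed here; these are standard structural-biology values
# and are fully configurable).

#' Default bond detection parameters
#'
#' Distance thresholds in Angstroms, angles in degrees, energy constants
#' in kcal/mol. All detection comparisons are closed (`<=` / `>=`), so a
#' contact at exactly a threshold is detected.
#'
#' @param ... Named overrides of nested fields, e.g.
#'   `bond_params(hbond = list(d_max = 3.2))` replaces only that field.
#' @return A nested list of class `bond_params` with components `hbond`,
#'   `vdw`, `ionic`, `pipi`, `pication`, `hydrophobic`, `ca_contact`,
#'   `seq_sep_generic`, `policy` and `include_his_cation`.
#' @export
bond_params <- function(...) {
  p <- list(
    hbond = list(d_max = 3.5, angle_min_deg = 120, require_h = TRUE,
                 D0 = 9.0, R0 = 2.8),
    vdw = list(surface_tol = 0.5, epsilon = 0.1),
    ionic = list(d_max = 4.5, coulomb_k = 332, dielectric_slope = 4),
    pipi = list(d_max = 6.5, parallel_max_deg = 30, tshape_min_deg = 60,
                E0 = 1.5, d_ref = 4.5),
    pication = list(d_max = 5.0, alpha_max_deg = 45, E0 = 2.0, d_ref = 4.0),
    hydrophobic = list(d_max = 4.5, E0 = 0.6, d_onset = 3.5),
    ca_contact = list(d_max = 8.0),
    seq_sep_generic = 3L,
    policy = "all",
    include_his_cation = FALSE
  )
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(p))
      stop(sprintf("bond_params: unknown field '%s'", nm), call. = FALSE)
    if (is.list(p[[nm]]) && is.list(over[[nm]])) {
      for (sub in names(over[[nm]])) {
        if (!sub %in% names(p[[nm]]))
          stop(sprintf("bond_params: unknown field '%s.%s'", nm, sub), call. = FALSE)
        p[[nm]][[sub]] <- over[[nm]][[sub]]
      }
    } else {
      p[[nm]] <- over[[nm]]
    }
  }
  validate_bond_params(structure(p, class = "bond_params"))
}

validate_bond_params <- function(p) {
  dists <- c(p$hbond$d_max, p$ionic$d_max, p$pipi$d_max, p$pication$d_max,
             p$hydrophobic$d_max, p$ca_contact$d_max)
  if (any(!is.finite(dists)) || any(dists <= 0))
    stop("bond_params: all distance thresholds must be > 0", call. = FALSE)
  angles <- c(p$hbond$angle_min_deg, p$pipi$parallel_max_deg,
              p$pipi$tshape_min_deg, p$pication$alpha_max_deg)
  if (any(angles < 0 | angles > 180))
    stop("bond_params: angles must lie in [0, 180]", call. = FALSE)
  if (p$seq_sep_generic < 1L)
    stop("bond_params: seq_sep_generic must be >= 1", call. = FALSE)
  if (!p$policy %in% c("all", "best-per-type", "best-overall"))
    stop("bond_params: policy must be all|best-per-type|best-overall", call. = FALSE)
  p
}

flatten_params <- function(p, prefix = "") {
  out <- character(0)
  for (nm in names(p)) {
    v <- p[[nm]]
    key <- if (prefix == "") nm else paste0(prefix, ".", nm)
    if (is.list(v)) out <- c(out, flatten_params(v, key))
    else out <- c(out, sprintf("%s=%s", key, format(v, digits = 15)))
  }
  out
}

#' Write bond parameters as a flat key=value config file
#'
#' @param params A `bond_params` object.
#' @param path Output path (or `""` to print to stdout).
#' @export
write_bond_params <- function(params, path) {
  lines <- flatten_params(unclass(params))
  if (identical(path, "")) cat(lines, sep = "\n") else writeLines(lines, path)
  invisible(path)
}

#' Read bond parameters from a flat key=value config file
#'
#' Unknown keys are an error; missing keys keep their defaults.
#'
#' @param path Path to a config file written by [write_bond_params()].
#' @return A `bond_params` object.
#' @export
read_bond_params <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  p <- unclass(bond_params())
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L)
      stop(sprintf("read_bond_params: malformed line '%s'", ln), call. = FALSE)
    keys <- strsplit(trimws(kv[1L]), ".", fixed = TRUE)[[1L]]
    val <- trimws(kv[2L])
    cur <- p
    for (k in keys) {
      if (is.null(cur[[k]]))
        stop(sprintf("read_bond_params: unknown key '%s'", kv[1L]), call. = FALSE)
      cur <- cur[[k]]
    }
    typed <- if (is.logical(cur)) as.logical(val)
    else if (is.character(cur)) val
    else if (is.integer(cur)) as.integer(val)
    else as.numeric(val)
    if (length(keys) == 1L) p[[keys]] <- typed else p[[keys[1L]]][[keys[2L]]] <- typed
  }
  validate_bond_params(structure(p, class = "bond_params"))
}
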