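#' Default run configuration
#'
#' The full configuration tree with every field at its default: probe
#' geometry/materials, environment, noise levels, Monte Carlo sizes and the
#' sweep selection. This is the schema [load_config()] validates against.
#'
#' @return A nested list of class `dhf_config`.
#' @export
dhf_config <- function() {
  structure(list(
    probe = list(k_s1 = 0.15, k_s2 = 0.15, d_s1_mm = 15, d_s2_mm = 30,
                 k_t = 0.37, d_t_mm = 2.5, h_sa = 6.1),
    env = list(cbt_c = 37, tamb_c = 25),
    noise = list(u_t_c = 0.053, u_dt_c = 2 * 0.0003, u_q_wm2 = 1.3,
                 u_h_wm2k = 0.12, ut_interpretation = "gaussian_sd",
                 h_noise_for_tt = TRUE),
    mc = list(n_reps = 10000, n_trials = 100, seed = 1),
    sweep = list(experiment = "e1", variants = dhf_variants()),
    output = list(dir = ".")
  ), class = "dhf_config")
}

#' Load and validate a run configuration
#'
#' Reads a YAML file, checks every block and key against the schema of
#' [dhf_config()] (unknown keys are rejected), overlays the file's values on
#' the defaults, and validates the physical parameters by constructing the
#' probe, environment and noise objects. An empty file yields the full
#' default configuration.
#'
#' @param path path to a YAML configuration file.
#' @return A validated `dhf_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  cfg <- dhf_config()
  if (is.null(user)) user <- list()
  if (!is.list(user)) stop("config must be a YAML mapping", call. = FALSE)
  bad_blocks <- setdiff(names(user), names(cfg))
  if (length(bad_blocks))
    stop("unknown config block: ", paste(bad_blocks, collapse = ", "),
         call. = FALSE)
  for (blk in names(user)) {
    bad_keys <- setdiff(names(user[[blk]]), names(cfg[[blk]]))
    if (length(bad_keys))
      stop("unknown key in '", blk, "' block: ",
           paste(bad_keys, collapse = ", "), call. = FALSE)
    cfg[[blk]][names(user[[blk]])] <- user[[blk]]
  }
  # constructing the objects enforces the physical invariants
  config_probe(cfg); config_env(cfg); config_noise(cfg)
  cfg
}

#' @describeIn load_config build the [dhf_probe()] a configuration describes.
#' @param cfg a `dhf_config` list.
#' @export
config_probe <- function(cfg) {
  p <- cfg$probe
  dhf_probe(k_s1 = p$k_s1, k_s2 = p$k_s2, d_s1_mm = p$d_s1_mm,
            d_s2_mm = p$d_s2_mm, k_t = p$k_t, d_t_mm = p$d_t_mm,
            h_sa = p$h_sa)
}

#' @describeIn load_config build the [dhf_env()] a configuration describes.
#' @export
config_env <- function(cfg) dhf_env(cbt = cfg$env$cbt_c, t_amb = cfg$env$tamb_c)

#' @describeIn load_config build the [dhf_noise()] a configuration describes.
#' @export
config_noise <- function(cfg) {
  n <- cfg$noise
  dhf_noise(u_t = n$u_t_c, u_dt = n$u_dt_c, u_q = n$u_q_wm2,
            u_h = n$u_h_wm2k, ut_interpretation = n$ut_interpretation,
            h_noise = n$h_noise_for_tt)
}

#' Write a sweep result table with a provenance manifest
#'
#' Writes the table as CSV (floats at 6 significant digits, header exactly
#' the table's columns) and a sibling `<name>_manifest.json` recording the
#' configuration echo, the master seed and the row count.
#'
#' @param table a `dhf_sweep` data.frame from [run_sweep()].
#' @param path output CSV path.
#' @param config optional `dhf_config` to echo into the manifest.
#' @return Invisibly, the manifest path.
#' @export
write_results <- function(table, path, config = NULL) {
  stopifnot(is.data.frame(table), nrow(table) > 0)
  out <- as.data.frame(table)
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  manifest <- list(
    seed = unique(table$seed),
    parameter = unique(as.character(table$parameter)),
    variants = unique(as.character(table$variant)),
    n_rows = nrow(table),
    n_reps = unique(table$n_reps), n_trials = unique(table$n_trials),
    nonfinite_total = sum(table$nonfinite_count),
    config = if (is.null(config)) NULL else unclass(config))
  mpath <- paste0(tools::file_path_sans_ext(path), "_manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(mpath)
}

#' Render a two-panel sweep figure
#'
#' Plots `mu_cbt` (left) and `su_cbt` (right) against the swept parameter,
#' one line per variant, and writes a PNG.
#'
#' @param table a `dhf_sweep` data.frame from [run_sweep()].
#' @param path output PNG path.
#' @param log axis spec as in [plot.default()] (e.g. `"y"`, `"xy"`, `""`).
#' @param width,height device size in pixels.
#' @return Invisibly, `path`.
#' @export
render_sweep_figure <- function(table, path, log = "y",
                                width = 1200, height = 500) {
  stopifnot(is.data.frame(table), nrow(table) > 0)
  grDevices::png(path, width = width, height = height, res = 110)
  on.exit(grDevices::dev.off())
  plot(table, log = log)
  invisible(path)
}

#' @export
plot.dhf_sweep <- function(x, log = "y", ...) {
  variants <- unique(x$variant)
  cols <- grDevices::hcl.colors(max(3, length(variants)), "Dark 3")
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (what in c("mu_cbt", "su_cbt")) {
    y <- x[[what]]
    ok <- is.finite(y) & (!grepl("y", log) | y > 0)
    graphics::plot(range(x$value), range(y[ok]), type = "n", log = log,
                   xlab = x$parameter[1], ylab = paste(what, "[degC]"),
                   main = what, ...)
    for (i in seq_along(variants)) {
      sub <- x[x$variant == variants[i], ]
      graphics::lines(sub$value, sub[[what]], col = cols[i], lwd = 1.5)
    }
    graphics::legend("topright", legend = variants, col = cols[seq_along(variants)],
                     lwd = 1.5, cex = 0.7, bty = "n")
  }
  invisible(x)
}
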