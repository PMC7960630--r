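# Scenario configuration files: a flat key-value text format with the
# five sections [grid], [params], [initial], [output] and [variants].
# Keys are named exactly as the corresponding model_params / grid fields;
# unknown keys are rejected. Variant lines read
#   name = field=value; field=value

fmt_num <- function(x) {
  if (is.logical(x)) return(if (x) "true" else "false")
  if (is.character(x)) return(x)
  paste(format(x, digits = 17, scientific = NA, trim = TRUE),
        collapse = ", ")
}

parse_value <- function(s) {
  s <- trimws(s)
  if (s %in% c("true", "TRUE")) return(TRUE)
  if (s %in% c("false", "FALSE")) return(FALSE)
  parts <- trimws(strsplit(s, ",", fixed = TRUE)[[1]])
  num <- suppressWarnings(as.numeric(parts))
  if (!anyNA(num)) return(num)
  s
}

config_keys <- list(
  grid = c("geometry", "x_min", "x_max", "n_cells"),
  params = c("N", "H", "K_S", "eta", "omega", "n_hill", "delta0", "zeta",
             "K_chi", "growth_on", "mode", "speed_factor"),
  initial = c("b_kind", "b_value", "b_center", "b_sigma", "b_normalize",
              "c_kind", "c_value", "c_max", "c_S", "c_N", "c_T0"),
  output = c("name", "c_mode", "t0", "t_snapshots", "front_threshold")
)

#' Write a scenario configuration file
#'
#' Serializes a [scenario_spec()] to the package's flat key-value config
#' format (sections `[grid]`, `[params]`, `[initial]`, `[output]`,
#' `[variants]`). The round trip through [read_scenario_config()] is
#' lossless: numbers are written with full double precision.
#'
#' @param spec A [scenario_spec()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(spec, path) {
  stopifnot(inherits(spec, "scenario_spec"))
  ln <- c("# chemokin scenario configuration", "", "[grid]")
  g <- spec$grid
  for (k in config_keys$grid)
    ln <- c(ln, paste(k, "=", fmt_num(g[[k]])))
  ln <- c(ln, "", "[params]")
  p <- unclass(spec$params)
  for (k in config_keys$params)
    ln <- c(ln, paste(k, "=", fmt_num(p[[k]])))
  ln <- c(ln, "", "[initial]")
  ini <- spec$initial
  emit_field <- function(prefix, d) {
    out <- paste0(prefix, "_kind = ", d$kind)
    map <- switch(d$kind,
      uniform = c(value = "value"),
      linear = c(C_max = "max"),
      pulse = c(S = "S", N = "N", T0 = "T0"),
      gaussian = c(value = "value", center = "center", sigma = "sigma",
                   normalize = "normalize"))
    for (k in names(map))
      out <- c(out, paste0(prefix, "_", map[[k]], " = ", fmt_num(d[[k]])))
    out
  }
  ln <- c(ln, emit_field("b", ini$B), emit_field("c", ini$C))
  ln <- c(ln, "", "[output]",
          paste("name =", spec$name),
          paste("c_mode =", spec$c_mode),
          paste("t0 =", fmt_num(spec$T0)),
          paste("t_snapshots =", fmt_num(spec$T_snapshots)),
          paste("front_threshold =", fmt_num(spec$front_threshold)))
  ln <- c(ln, "", "[variants]")
  for (nm in names(spec$variants)) {
    ov <- spec$variants[[nm]]
    ln <- c(ln, paste(nm, "=",
                      paste(names(ov), vapply(ov, fmt_num, ""),
                            sep = "=", collapse = "; ")))
  }
  writeLines(ln, path)
  invisible(path)
}

#' Read a scenario configuration file
#'
#' Parses the config format written by [write_scenario_config()] and
#' rebuilds the [scenario_spec()] (including its initial fields). Unknown
#' sections or keys raise an error.
#'
#' @param path Path to a config file.
#' @return A [scenario_spec()].
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path,
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  section <- NULL
  store <- list(grid = list(), params = list(), initial = list(),
                output = list(), variants = list())
  for (l in lines) {
    if (grepl("^\\[.*\\]$", l)) {
      section <- sub("^\\[(.*)\\]$", "\\1", l)
      if (!section %in% names(store))
        stop("unknown config section: [", section, "]", call. = FALSE)
      next
    }
    if (is.null(section))
      stop("config line outside any section: ", l, call. = FALSE)
    kv <- regmatches(l, regexpr("=", l, fixed = TRUE), invert = TRUE)[[1]]
    if (length(kv) != 2L)
      stop("malformed config line: ", l, call. = FALSE)
    key <- trimws(kv[1])
    if (section != "variants" && !key %in% config_keys[[section]])
      stop("unknown key '", key, "' in section [", section, "]",
           call. = FALSE)
    store[[section]][[key]] <- if (section == "variants") kv[2]
                               else parse_value(kv[2])
  }
  need <- function(sec, key) {
    v <- store[[sec]][[key]]
    if (is.null(v)) stop("missing config key '", key, "' in [", sec, "]",
                         call. = FALSE)
    v
  }
  grid <- make_grid(need("grid", "geometry"), need("grid", "x_min"),
                    need("grid", "x_max"), need("grid", "n_cells"))
  params <- do.call(model_params, store$params)
  read_field <- function(prefix) {
    kind <- need("initial", paste0(prefix, "_kind"))
    pick <- function(suffix) store$initial[[paste0(prefix, "_", suffix)]]
    switch(kind,
      uniform = list(kind = "uniform", value = pick("value")),
      linear = list(kind = "linear", C_max = pick("max")),
      pulse = list(kind = "pulse", S = pick("S"), N = pick("N"),
                   T0 = pick("T0")),
      gaussian = list(kind = "gaussian", center = pick("center"),
                      sigma = pick("sigma"),
                      normalize = pick("normalize"),
                      value = pick("value")),
      stop("unknown initial-field kind: ", kind, call. = FALSE))
  }
  variants <- lapply(store$variants, function(s) {
    terms <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    terms <- terms[nzchar(terms)]
    ov <- list()
    for (t in terms) {
      kv <- trimws(strsplit(t, "=", fixed = TRUE)[[1]])
      if (length(kv) != 2L)
        stop("malformed variant entry: ", t, call. = FALSE)
      ov[[kv[1]]] <- parse_value(kv[2])
    }
    ov
  })
  scenario_spec(
    name = need("output", "name"), grid = grid, params = params,
    initial = list(B = read_field("b"), C = read_field("c")),
    c_mode = need("output", "c_mode"),
    T_snapshots = need("output", "t_snapshots"),
    variants = variants,
    T0 = store$output$t0 %||% 0,
    front_threshold = store$output$front_threshold %||% 0.1)
}
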