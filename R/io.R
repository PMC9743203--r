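# Plain-text file formats: first-passage CSV (one passage per row with a
# `# key=value` metadata header) and flat key=value potential configs.
# All files store ps and 1/ps; ns values are accepted on read only with an
# explicit unit suffix and converted.

# "0.1 ns", "0.1ns^-1", "2.5 ps" -> value in ps or 1/ps
.parse_unit_value <- function(txt) {
  txt <- trimws(txt)
  m <- regmatches(txt, regexec(
    "^([0-9.eE+-]+)\\s*(ns|ps)?(\\^?-1)?$", txt))[[1]]
  if (length(m) == 0) return(suppressWarnings(as.numeric(txt)))
  val <- as.numeric(m[2])
  unit <- m[3]
  inverse <- nzchar(m[4])
  if (!nzchar(unit) || unit == "ps") return(val)
  # ns: times scale by 1000, rates by 1/1000
  if (inverse) val * 1e-3 else val * 1e3
}

#' Write a first-passage sample set to CSV
#'
#' Comment header lines `# key=value` carry the provenance (protocol,
#' rate/period, potential form, seed, temperature, dt, n, censored count),
#' followed by rows `tau_ps,censored,resets`. Rates are serialized in 1/ps
#' and times in ps.
#'
#' @param samples An [fpt_samples()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fpt_csv <- function(samples, path) {
  stopifnot(inherits(samples, "fpt_samples"))
  md <- samples$metadata
  hdr <- c(protocol = samples$protocol$kind)
  if (samples$protocol$kind == "poisson")
    hdr["rate"] <- format(samples$protocol$rate, digits = 17)
  if (samples$protocol$kind == "sharp")
    hdr["period"] <- format(samples$protocol$period, digits = 17)
  for (k in c("potential", "seed", "temperature", "dt", "model"))
    if (!is.null(md[[k]])) hdr[k] <- as.character(md[[k]])
  hdr["n"] <- samples$n
  hdr["censored"] <- sum(samples$censored)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", names(hdr), "=", unname(hdr)), con)
  writeLines("tau_ps,censored,resets", con)
  resets <- md$resets
  if (is.null(resets)) resets <- rep(NA_integer_, samples$n)
  writeLines(paste(format(samples$tau, digits = 17, trim = TRUE),
                   as.integer(samples$censored), resets, sep = ","), con)
  invisible(path)
}

#' Read a first-passage sample set from CSV
#'
#' Parses the `# key=value` header into provenance (the protocol entry is
#' required: inference needs to know the reference rate), validates that
#' passage times are non-negative, and counts censored rows. Rates/periods
#' given in ns (explicit suffix, e.g. `rate=0.1ns^-1`) are converted to the
#' internal ps units.
#'
#' @param path Input file path.
#' @return An [fpt_samples()] object.
#' @export
read_fpt_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  kv <- list()
  for (l in lines[hdr_idx]) {
    l <- sub("^#\\s*", "", l)
    eq <- regexpr("=", l, fixed = TRUE)
    if (eq > 0)
      kv[[trimws(substr(l, 1, eq - 1))]] <- trimws(substr(l, eq + 1,
                                                          nchar(l)))
  }
  if (is.null(kv$protocol))
    stop("missing protocol metadata in ", path,
         " (a '# protocol=...' header is required)")
  protocol <- switch(kv$protocol,
    none = reset_protocol("none"),
    poisson = {
      if (is.null(kv$rate)) stop("poisson protocol header lacks rate")
      reset_protocol("poisson", rate = .parse_unit_value(kv$rate))
    },
    sharp = {
      if (is.null(kv$period)) stop("sharp protocol header lacks period")
      reset_protocol("sharp", period = .parse_unit_value(kv$period))
    },
    stop("unknown protocol '", kv$protocol, "' in ", path))
  body <- lines[-hdr_idx]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2) stop("no data rows in ", path)
  df <- read.table(text = paste(body, collapse = "\n"), header = TRUE,
                   sep = ",")
  if (!"tau_ps" %in% names(df)) stop("missing tau_ps column in ", path)
  if (any(!is.finite(df$tau_ps)) || any(df$tau_ps < 0))
    stop("format error: negative or non-finite tau in ", path)
  censored <- if ("censored" %in% names(df)) df$censored > 0 else FALSE
  md <- kv[setdiff(names(kv), c("protocol", "rate", "period", "n",
                                "censored"))]
  for (k in c("temperature", "dt", "seed"))
    if (!is.null(md[[k]])) md[[k]] <- .parse_unit_value(md[[k]])
  if ("resets" %in% names(df)) md$resets <- df$resets
  fpt_samples(df$tau_ps, censored = censored, protocol = protocol,
              metadata = md)
}

#' Read a potential configuration file
#'
#' Flat `key = value` text: `form`, `temperature`, optional `box.<i> = lo hi`
#' lines, and `param.<name>` entries overriding the calibrated defaults.
#'
#' @param path Input file path.
#' @return An [fpt_potential()].
#' @export
read_potential_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- list()
  for (l in lines) {
    eq <- regexpr("=", l, fixed = TRUE)
    if (eq < 0) stop("malformed config line: ", l)
    kv[[trimws(substr(l, 1, eq - 1))]] <- trimws(substr(l, eq + 1, nchar(l)))
  }
  if (is.null(kv$form)) stop("config lacks 'form'")
  params <- list()
  box <- NULL
  for (k in names(kv)) {
    if (startsWith(k, "param.")) {
      params[[substring(k, 7)]] <- as.numeric(kv[[k]])
    } else if (startsWith(k, "box.")) {
      i <- as.integer(substring(k, 5))
      b <- as.numeric(strsplit(trimws(kv[[k]]), "\\s+")[[1]])
      if (is.null(box)) box <- list()
      box[[i]] <- b
    }
  }
  if (!is.null(box)) box <- do.call(rbind, box)
  fpt_potential(kv$form, params = params,
                dim = if (!is.null(kv$dim)) as.integer(kv$dim) else NULL,
                box = box,
                temperature = if (!is.null(kv$temperature))
                  as.numeric(kv$temperature) else 300)
}
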