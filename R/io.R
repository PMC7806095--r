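# CSV writers that survive a round trip exactly: doubles are printed with 17
# significant digits so read.csv recovers the same binary values.
.writeTableFull <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Read and write flat key-value configuration files
#'
#' The schema is one \code{key = value} pair per line (keys: L, N, Pu, knl,
#' Psl, c, steps, seed, sampleInterval); blank lines and \code{#} comments
#' are ignored.  The same keys are exposed as command-line flags by the
#' \code{anttower} script.
#'
#' @param path file path.
#' @return \code{readConfig}: a named list of numeric values.
#' @export
readConfig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1L])
  vals <- lapply(kv, function(p) {
    v <- suppressWarnings(as.numeric(trimws(p[2L])))
    if (is.na(v)) stop("non-numeric config value for key ", trimws(p[1L]))
    v
  })
  setNames(vals, vapply(kv, function(p) trimws(p[1L]), character(1)))
}

#' @rdname readConfig
#' @param params a [SimParams-class] (or named list) to serialize.
#' @return \code{writeConfig}: the path, invisibly.
#' @export
writeConfig <- function(params, path) {
  if (is(params, "SimParams")) params <- as.list(params)
  writeLines(sprintf("%s = %.17g", names(params), as.numeric(params)), path)
  invisible(path)
}

#' @rdname readConfig
#' @param config a named list from \code{readConfig} (or a path).
#' @return \code{configParams}: the corresponding [SimParams-class].
#' @export
configParams <- function(config) {
  if (is.character(config)) config <- readConfig(config)
  known <- c("L", "N", "Pu", "knl", "Psl", "c", "steps", "seed",
             "sampleInterval")
  bad <- setdiff(names(config), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(simParams, config)
}

#' Persist and reload a simulation run
#'
#' Writes a directory of plain-text artifacts: \code{manifest.json} (all
#' parameters, seed, package version, sample times), \code{series.csv}
#' (largest-tower time series), \code{height.csv} (final height map),
#' \code{agents.csv} (final agent table) and, when the run recorded maps,
#' \code{maps.csv} (sparse long-format height-map stack: t, x, y, h).
#' \code{readRunRecord} reverses the process exactly.
#'
#' @param run a [SimRun-class].
#' @param dir output directory (created if needed).
#' @return \code{writeRunRecord}: \code{dir}, invisibly.
#' @export
writeRunRecord <- function(run, dir) {
  stopifnot(is(run, "SimRun"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- runParams(run)
  manifest <- list(package = "anttower",
                   version = as.character(packageVersion("anttower")),
                   params = as.list(p),
                   t_final = run@world@t,
                   sample_times = run@sampleTimes,
                   has_maps = length(run@maps) > 0,
                   files = c("series.csv", "height.csv", "agents.csv"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .writeTableFull(simSeries(run), file.path(dir, "series.csv"))
  write.table(heightMap(run), file.path(dir, "height.csv"), sep = ",",
              row.names = FALSE, col.names = FALSE)
  .writeTableFull(agents(finalWorld(run)), file.path(dir, "agents.csv"))
  if (length(run@maps)) {
    long <- do.call(rbind, lapply(seq_along(run@maps), function(k) {
      m <- run@maps[[k]]
      nz <- which(m > 0, arr.ind = TRUE)
      if (nrow(nz) == 0L) return(NULL)   # empty frames rebuild as all-zero
      data.frame(t = run@sampleTimes[k], x = nz[, 1L] - 1L,
                 y = nz[, 2L] - 1L, h = m[nz])
    }))
    if (is.null(long))
      long <- data.frame(t = numeric(), x = integer(), y = integer(),
                         h = integer())
    .writeTableFull(long, file.path(dir, "maps.csv"))
  }
  invisible(dir)
}

#' @rdname writeRunRecord
#' @return \code{readRunRecord}: the reconstructed [SimRun-class].
#' @export
readRunRecord <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  params <- do.call(simParams, as.list(manifest$params))
  series <- read.csv(file.path(dir, "series.csv"))
  hm <- as.matrix(read.csv(file.path(dir, "height.csv"), header = FALSE))
  dimnames(hm) <- NULL
  storage.mode(hm) <- "integer"
  ag <- read.csv(file.path(dir, "agents.csv"),
                 colClasses = c(state = "character"))
  world <- worldState(hm, ag, t = manifest$t_final)
  maps <- list()
  if (isTRUE(manifest$has_maps)) {
    long <- read.csv(file.path(dir, "maps.csv"))
    L <- params@L
    maps <- lapply(manifest$sample_times, function(tt) {
      m <- matrix(0L, L, L)
      sub <- long[long$t == tt, , drop = FALSE]
      m[cbind(sub$x + 1L, sub$y + 1L)] <- as.integer(sub$h)
      m
    })
  }
  new("SimRun", params = params, world = world, series = series,
      maps = maps, sampleTimes = as.numeric(manifest$sample_times))
}
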