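#' Write / read a trajectory as TSV
#'
#' Plain-text dialect: '#'-prefixed header lines carry the seed, parameter
#' digest, stride and phase boundaries; then a tab-separated table with
#' columns \code{time}, \code{chem}, \code{x_-6.5 ... x_6.5}, \code{y1},
#' \code{y2}.  Full double precision is preserved, so write-then-read
#' round-trips the snapshots exactly.
#'
#' @param traj a \code{\linkS4class{Trajectory}}.
#' @param path file path.
#' @return \code{readTrajectoryTsv}: a \code{\linkS4class{Trajectory}}.
#' @export
writeTrajectoryTsv <- function(traj, path) {
  stopifnot(is(traj, "Trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# twistslide trajectory"),
    paste0("# seed\t", traj@seed),
    paste0("# digest\t", traj@paramsDigest),
    paste0("# stride\t", format(traj@stride, digits = 17)),
    paste0("# phase_bounds\t",
           paste(format(traj@phaseBounds, digits = 17), collapse = ",")),
    paste0("# final\t",
           paste(format(traj@final, digits = 17), collapse = ","))), con)
  df <- data.frame(time = traj@times, chem = traj@chem, traj@coords,
                   check.names = FALSE)
  write.table(format(df, digits = 17, trim = TRUE), con, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrajectoryTsv
#' @export
readTrajectoryTsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- function(key, default = "") {
    h <- grep(paste0("^# ", key, "\t"), hdr, value = TRUE)
    if (!length(h)) return(default)
    sub(paste0("^# ", key, "\t"), "", h[1])
  }
  df <- read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                   sep = "\t", check.names = FALSE)
  co <- as.matrix(df[, -(1:2)])
  colnames(co) <- coordNames()
  pb <- meta("phase_bounds")
  fin <- meta("final")
  new("Trajectory",
      times = df$time, coords = co, chem = as.character(df$chem),
      phaseBounds = if (nzchar(pb)) as.numeric(strsplit(pb, ",")[[1]])
                    else numeric(0),
      final = if (nzchar(fin))
                setNames(as.numeric(strsplit(fin, ",")[[1]]), coordNames())
              else co[nrow(co), ],
      seed = as.integer(meta("seed", "0")),
      paramsDigest = meta("digest"),
      stride = as.numeric(meta("stride", "0.05")))
}
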