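#' Particle cloud on the mouth-exit plane
#'
#' A `particle_cloud` holds the 2-D positions (in mm) of exhaled tracer
#' particles recorded on the circular mouth-exit plane from one breath test,
#' together with a model label, a replicate id and the plane diameter.
#' Coordinates use the disk center as origin, x rightward and y upward; the
#' closed disk of diameter `diameter` is the valid domain.
#'
#' @param x,y Numeric vectors of particle coordinates in mm.
#' @param diameter Diameter of the mouth-exit plane in mm.
#' @param model Model label (e.g. "A".."D", or a severity label "D0".."D3").
#' @param replicate Integer replicate (breath-test) id.
#' @param tag Optional per-particle tag (e.g. marking particles released from
#'   a region of interest); recycled logical/character vector or `NULL`.
#' @return An object of class `particle_cloud`.
#' @examples
#' cl <- particle_cloud(c(0, 1), c(0, -2), diameter = 20)
#' n_particles(cl)
#' @export
particle_cloud <- function(x, y, diameter = 20, model = "A", replicate = 1L,
                           tag = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 1L) stopf("a particle cloud needs at least one particle")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stopf("non-finite particle coordinates")
  if (!is.numeric(diameter) || diameter <= 0) stopf("diameter must be > 0")
  r <- sqrt(x^2 + y^2)
  bad <- which(r > diameter / 2 + 1e-9)
  if (length(bad) > 0L)
    stopf("%d particle(s) outside the disk (first at row %d, r = %.4f mm > %.4f mm)",
          length(bad), bad[1L], r[bad[1L]], diameter / 2)
  if (!is.null(tag)) tag <- rep_len(tag, length(x))
  structure(list(x = x, y = y, diameter = diameter,
                 model = as.character(model),
                 replicate = as.integer(replicate), tag = tag),
            class = "particle_cloud")
}

#' @rdname particle_cloud
#' @param cloud A `particle_cloud`.
#' @export
n_particles <- function(cloud) length(cloud$x)

#' @export
print.particle_cloud <- function(x, ...) {
  cat(sprintf("particle_cloud: %d particles, disk %.1f mm, model %s, replicate %d\n",
              n_particles(x), x$diameter, x$model, x$replicate))
  invisible(x)
}

#' Read and write particle clouds as delimited text
#'
#' Files carry one row per particle with columns `x_mm`, `y_mm` and optional
#' `model`, `replicate`, `tag` columns. `read_particles()` validates that all
#' points lie inside the disk; with `strict = FALSE`, out-of-disk points are
#' dropped with a warning instead of raising an error.
#'
#' @param path Path of the delimited text file.
#' @param diameter Disk diameter in mm used for mask validation.
#' @param sep Field separator (default comma).
#' @param strict If `TRUE` (default) an out-of-disk point is an error naming
#'   the offending row; if `FALSE` such points are dropped with a warning.
#' @return `read_particles()` returns a `particle_cloud`; `write_particles()`
#'   returns `path` invisibly.
#' @export
read_particles <- function(path, diameter = 20, sep = ",", strict = TRUE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stopf("empty particle file: %s", path)
  need <- c("x_mm", "y_mm")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stopf("missing column(s) %s in %s", paste(miss, collapse = ", "), path)
  if (!is.numeric(df$x_mm) || !is.numeric(df$y_mm))
    stopf("non-numeric coordinates in %s", path)
  r <- sqrt(df$x_mm^2 + df$y_mm^2)
  out <- which(r > diameter / 2 + 1e-9)
  if (length(out) > 0L) {
    if (strict)
      stopf("row %d of %s lies outside the disk (r = %.4f mm > %.4f mm)",
            out[1L], path, r[out[1L]], diameter / 2)
    warning(sprintf("dropping %d out-of-disk point(s)", length(out)))
    df <- df[-out, , drop = FALSE]
  }
  particle_cloud(df$x_mm, df$y_mm, diameter = diameter,
                 model = if ("model" %in% names(df)) df$model[1L] else "A",
                 replicate = if ("replicate" %in% names(df)) df$replicate[1L] else 1L,
                 tag = if ("tag" %in% names(df)) df$tag else NULL)
}

#' @rdname read_particles
#' @param cloud A `particle_cloud`.
#' @export
write_particles <- function(cloud, path, sep = ",") {
  df <- data.frame(x_mm = cloud$x, y_mm = cloud$y,
                   model = cloud$model, replicate = cloud$replicate)
  if (!is.null(cloud$tag)) df$tag <- cloud$tag
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
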