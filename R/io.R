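# Plain-JSON array containers.
#
# Every on-disk artifact (phantom, field set, excitation) is a single JSON
# file: {"container": <type>, "version": 1, "attrs": {...}, "datasets":
# {name: {"dim": [...], "storage": "double"|"complex"|"logical",
# "data": [...column-major flat...]}}}. Complex data is stored as parallel
# "re"/"im" flat arrays. Numbers are written with 17 significant digits so a
# save -> load round trip is bit-identical; any external tool that writes the
# same layout is read identically.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[!is.finite(x)] <- "null"
  out
}

json_scalar <- function(x) {
  if (is.character(x)) paste0("\"", gsub("\"", "\\\\\"", x), "\"")
  else if (is.logical(x)) ifelse(x, "true", "false")
  else if (is.integer(x)) sprintf("%d", x)
  else fmt_num(x)
}

json_value <- function(x) {
  if (length(x) == 1 && is.null(dim(x))) json_scalar(x)
  else paste0("[", paste(json_scalar(x), collapse = ","), "]")
}

dataset_json <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  if (is.complex(x)) {
    body <- paste0("\"storage\":\"complex\",\"re\":[",
                   paste(fmt_num(Re(x)), collapse = ","),
                   "],\"im\":[", paste(fmt_num(Im(x)), collapse = ","), "]")
  } else if (is.logical(x)) {
    body <- paste0("\"storage\":\"logical\",\"data\":[",
                   paste(ifelse(x, "true", "false"), collapse = ","), "]")
  } else {
    body <- paste0("\"storage\":\"double\",\"data\":[",
                   paste(fmt_num(as.numeric(x)), collapse = ","), "]")
  }
  paste0("{\"dim\":[", paste(d, collapse = ","), "],", body, "}")
}

write_container <- function(path, type, attrs, datasets) {
  a <- paste(vapply(names(attrs), function(k)
    paste0("\"", k, "\":", json_value(attrs[[k]])), character(1)),
    collapse = ",")
  ds <- paste(vapply(names(datasets), function(k)
    paste0("\"", k, "\":", dataset_json(datasets[[k]])), character(1)),
    collapse = ",")
  txt <- paste0("{\"container\":\"", type, "\",\"version\":1,",
                "\"attrs\":{", a, "},\"datasets\":{", ds, "}}")
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

read_container <- function(path, type) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyMatrix = FALSE)
  if (!identical(obj$container, type))
    stop(sprintf("not a %s container: %s", type, path))
  obj$datasets <- lapply(obj$datasets, function(d) {
    dm <- as.integer(d$dim)
    x <- if (identical(d$storage, "complex")) {
      complex(real = as.numeric(d$re), imaginary = as.numeric(d$im))
    } else if (identical(d$storage, "logical")) as.logical(d$data)
    else as.numeric(d$data)
    if (length(x) != prod(dm))
      stop(sprintf("dataset in %s has %d values but dim %s", path,
                   length(x), paste(dm, collapse = "x")))
    if (length(dm) > 1) dim(x) <- dm
    x
  })
  obj
}

#' Write / read a phantom container
#'
#' Phantoms are stored as a plain-JSON array container with datasets `eps_r`,
#' `sigma`, `breast_mask`, `interior_mask` and attributes recording the grid
#' and generation parameters. The round trip is bit-identical.
#'
#' @param phantom a `phantom_grid`.
#' @param path file path.
#' @return `read_phantom()` returns the `phantom_grid`.
#' @export
write_phantom <- function(phantom, path) {
  stopifnot(inherits(phantom, "phantom_grid"))
  attrs <- list(n_rows = phantom$grid$n_rows, n_cols = phantom$grid$n_cols,
                pixel_mm = phantom$grid$pixel_mm, seed = phantom$seed,
                heterogeneity = phantom$heterogeneity,
                semi_axes_mm = phantom$semi_axes_mm,
                skin_mm = phantom$skin_mm)
  if (!is.null(phantom$tumor)) {
    attrs$tumor_center <- phantom$tumor$center
    attrs$tumor_radius_mm <- phantom$tumor$radius_mm
  }
  write_container(path, "mhfocus_phantom", attrs,
                  list(eps_r = phantom$eps_r, sigma = phantom$sigma,
                       breast_mask = phantom$breast_mask,
                       interior_mask = phantom$interior_mask))
}

#' @rdname write_phantom
#' @export
read_phantom <- function(path) {
  obj <- read_container(path, "mhfocus_phantom")
  a <- obj$attrs
  g <- grid_spec(a$n_rows, a$n_cols, a$pixel_mm)
  tum <- if (!is.null(a$tumor_center))
    list(center = as.numeric(a$tumor_center),
         radius_mm = as.numeric(a$tumor_radius_mm))
  structure(list(grid = g, eps_r = obj$datasets$eps_r,
                 sigma = obj$datasets$sigma,
                 breast_mask = obj$datasets$breast_mask,
                 interior_mask = obj$datasets$interior_mask,
                 tumor = tum, seed = as.integer(a$seed),
                 heterogeneity = as.numeric(a$heterogeneity),
                 semi_axes_mm = as.numeric(a$semi_axes_mm),
                 skin_mm = as.numeric(a$skin_mm)),
            class = "phantom_grid")
}

#' Export a matrix-valued map as CSV for inspection
#'
#' @param m a numeric or logical matrix (e.g. `phantom$sigma`).
#' @param path file path.
#' @export
write_map_csv <- function(m, path) {
  utils::write.table(m, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
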