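## Plain-text, versioned containers: one file per map (header + axis +
## pixel-per-row spectra), integer-label mask grids, TSV count tables, and a
## YAML cohort manifest. Everything is written so that read(write(x)) is the
## identity (fwrite/fread round-trip doubles exactly).

HYPERMAP_MAGIC <- "# hypermap v1"
N_HEADER <- 7L

# %.17g guarantees the shortest-read-back-exact decimal for doubles, which
# fwrite's 15-significant-digit output does not.
format_row_tsv <- function(m) {
  cols <- lapply(seq_len(ncol(m)), function(j) sprintf("%.17g", m[, j]))
  do.call(paste, c(cols, sep = "\t"))
}

#' Write a hyperspectral map to a delimited text container
#'
#' Layout: a 7-line commented header (`# hypermap v1`, map_id, condition,
#' height, width, pixel_size, channels), one tab-separated line holding the
#' wavenumber axis, then `height * width` tab-separated pixel spectra in
#' row-major order.
#'
#' @param map A [hyper_map()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hypermap <- function(map, path) {
  stopifnot(inherits(map, "hyper_map"))
  hdr <- c(HYPERMAP_MAGIC,
           paste0("# map_id: ", map$map_id),
           paste0("# condition: ", map$condition),
           paste0("# height: ", map$height),
           paste0("# width: ", map$width),
           paste0("# pixel_size: ", format(map$pixel_size, digits = 17)),
           paste0("# channels: ", length(map$axis)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(format_row_tsv(rbind(as.numeric(map$axis))), con)
  writeLines(format_row_tsv(map_spectra(map)), con)
  invisible(path)
}

header_field <- function(lines, key, path) {
  pat <- paste0("^# ", key, ": ")
  hit <- grep(pat, lines, value = TRUE)
  if (length(hit) != 1)
    stop("malformed hypermap header in ", path, ": missing '", key, "'")
  sub(pat, "", hit)
}

#' Read a hyperspectral map container
#'
#' @param path File written by [write_hypermap()].
#' @return A [hyper_map()].
#' @export
read_hypermap <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  hdr <- readLines(path, n = N_HEADER)
  if (length(hdr) < N_HEADER || hdr[1] != HYPERMAP_MAGIC)
    stop("not a supported hypermap container: ", path)
  h <- as.integer(header_field(hdr, "height", path))
  w <- as.integer(header_field(hdr, "width", path))
  C <- as.integer(header_field(hdr, "channels", path))
  body <- data.table::fread(path, sep = "\t", skip = N_HEADER,
                            header = FALSE, colClasses = "double")
  if (ncol(body) != C)
    stop("format error in ", path, ": header declares ", C,
         " channels but rows have ", ncol(body))
  axis <- as.numeric(as.matrix(body[1, ]))
  px <- as.matrix(body[-1, ])
  if (nrow(px) != h * w)
    stop("format error in ", path, ": header declares ", h, "x", w, " = ",
         h * w, " pixels but file has ", nrow(px))
  cube <- aperm(array(px, c(w, h, C)), c(2, 1, 3))
  hyper_map(cube, axis, header_field(hdr, "map_id", path),
            header_field(hdr, "condition", path),
            as.numeric(header_field(hdr, "pixel_size", path)))
}

#' Write / read an integer compartment mask grid
#'
#' Masks are `height` lines of `width` tab-separated integer labels
#' (0 background, 1 cytoplasm, 2 nucleus), row-major like the maps.
#'
#' @param mask Integer matrix.
#' @param path File path.
#' @return `path` (write) or an integer matrix (read).
#' @export
write_mask <- function(mask, path) {
  data.table::fwrite(data.table::as.data.table(mask), path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  m <- as.matrix(data.table::fread(path, sep = "\t", header = FALSE))
  if (anyNA(m) || any(m != round(m))) stop("mask must be integer labels: ", path)
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  m
}

#' Write a simulated cohort to a directory container
#'
#' One directory per cohort: `manifest.yaml` (format version, seed,
#' conditions, per-map file names), one hypermap container per map, and,
#' when ground truth is supplied, one mask grid per map.
#'
#' @param maps Named list of [hyper_map()].
#' @param dir Output directory (created if needed).
#' @param truth Optional `synthetic_truth` from [simulate_cohort()].
#' @param seed Seed recorded in the manifest.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(maps, dir, truth = NULL, seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(maps, function(m) {
    f <- paste0(m$map_id, ".map.tsv")
    write_hypermap(m, file.path(dir, f))
    e <- list(id = m$map_id, condition = m$condition, file = f)
    if (!is.null(truth) && !is.null(truth$masks[[m$map_id]])) {
      e$mask <- paste0(m$map_id, ".mask.txt")
      write_mask(truth$masks[[m$map_id]], file.path(dir, e$mask))
    }
    e
  })
  manifest <- list(format = "ramanxome-cohort", version = 1L,
                   seed = seed %||% truth$seed, n_maps = length(maps),
                   maps = unname(entries))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a cohort directory container
#'
#' @param dir Directory written by [write_cohort()].
#' @return List with `maps` (named list of [hyper_map()]), `masks` (named
#'   list or `NULL`), and the parsed `manifest`.
#' @export
read_cohort <- function(dir) {
  mf_path <- file.path(dir, "manifest.yaml")
  if (!file.exists(mf_path)) stop("no cohort manifest in ", dir)
  manifest <- yaml::read_yaml(mf_path)
  if (!identical(manifest$format, "ramanxome-cohort"))
    stop("unsupported cohort format in ", dir)
  maps <- list(); masks <- list()
  for (e in manifest$maps) {
    maps[[e$id]] <- read_hypermap(file.path(dir, e$file))
    if (!is.null(e$mask)) masks[[e$id]] <- read_mask(file.path(dir, e$mask))
  }
  list(maps = maps, masks = if (length(masks)) masks else NULL,
       manifest = manifest)
}

#' Read a transcript count table
#'
#' Tab-separated, first column transcript ids, one column per sample,
#' header row of sample ids. Row order is preserved. Condition labels come
#' from `conditions` or, when `NULL`, from the sample-id prefix before the
#' first `-` (e.g. `D0-1`).
#'
#' @param path TSV path.
#' @param conditions Optional character vector/named vector of condition
#'   labels per sample.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, conditions = NULL) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  ids <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1])
  if (!is.numeric(m)) {
    bad <- which(apply(dt[, -1], 1, function(r) any(is.na(suppressWarnings(as.numeric(r))))))
    stop("non-numeric count at row ", bad[1], " of ", path)
  }
  if (anyNA(m)) stop("missing count at row ", which(rowSums(is.na(m)) > 0)[1],
                     " of ", path)
  if (any(m < 0)) stop("negative count at row ",
                       which(rowSums(m < 0) > 0)[1], " of ", path)
  if (any(m != round(m))) stop("non-integer count at row ",
                               which(rowSums(m != round(m)) > 0)[1], " of ", path)
  rownames(m) <- ids
  if (is.null(conditions)) conditions <- sub("-.*$", "", colnames(m))
  count_matrix(m, conditions)
}

#' Write a transcript count table
#'
#' @param x A [count_matrix()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  dt <- data.table::data.table(transcript_id = rownames(x$counts))
  for (s in colnames(x$counts)) dt[[s]] <- x$counts[, s]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
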