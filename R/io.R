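#' Write / read a per-vertex label map
#'
#' Plain-text format: comment header declaring the vertex count, hemisphere
#' split, an optional label table (index:name:color triplets) and the
#' provenance hash, followed by one label per line (integer, or NA for
#' excluded vertices). Round trips are lossless.
#'
#' @param labels integer vector (or `vertex_assignment`).
#' @param path output file.
#' @param n_left number of left-hemisphere vertices (serialized first).
#' @param label_table optional data.frame (label, name, color).
#' @param config_hash optional provenance string.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(labels, path, n_left = NULL, label_table = NULL,
                            config_hash = NULL) {
  if (inherits(labels, "vertex_assignment")) labels <- labels$labels
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# netmapr labels v1",
    paste0("# n_vertices: ", length(labels)),
    paste0("# n_left: ", if (is.null(n_left)) length(labels) %/% 2 else n_left),
    paste0("# label_table: ", if (is.null(label_table)) "" else
      paste(sprintf("%d:%s:%s", label_table$label, label_table$name,
                    label_table$color), collapse = ",")),
    paste0("# config_hash: ", if (is.null(config_hash)) "NA" else config_hash)
  ), con)
  writeLines(ifelse(is.na(labels), "NA", as.character(labels)), con)
  invisible(path)
}

#' @rdname write_label_map
#' @param expected_vertices if given, error unless the file's declared count
#'   matches (error names both counts).
#' @export
read_label_map <- function(path, expected_vertices = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    x <- sub(paste0("^# ", key, ": "), "",
             grep(paste0("^# ", key, ":"), hdr, value = TRUE)[1])
    x
  }
  n_vertices <- as.integer(get_field("n_vertices"))
  if (is.na(n_vertices)) stop("not a netmapr label file: ", path)
  if (!is.null(expected_vertices) && n_vertices != expected_vertices) {
    stop("vertex count mismatch: file declares ", n_vertices,
         " but surface has ", expected_vertices)
  }
  body <- lines[!grepl("^#", lines)]
  if (length(body) != n_vertices) {
    offset <- sum(nchar(lines[seq_len(length(hdr) + length(body))])) +
      length(hdr) + length(body)
    stop("truncated label file: expected ", n_vertices, " labels, found ",
         length(body), " (file ends at byte offset ~", offset, ")")
  }
  labels <- suppressWarnings(as.integer(body))
  labels[body == "NA"] <- NA_integer_
  lt_raw <- get_field("label_table")
  label_table <- NULL
  if (!is.na(lt_raw) && nzchar(lt_raw)) {
    parts <- strsplit(strsplit(lt_raw, ",")[[1]], ":")
    label_table <- data.frame(
      label = as.integer(vapply(parts, `[`, "", 1)),
      name = vapply(parts, `[`, "", 2),
      color = vapply(parts, `[`, "", 3),
      stringsAsFactors = FALSE)
  }
  structure(labels,
            n_left = as.integer(get_field("n_left")),
            label_table = label_table,
            config_hash = get_field("config_hash"))
}

#' Write / read a dense real matrix as text
#'
#' Comment header with dimensions, then tab-separated rows at full double
#' precision (`%.17g`), so 64-bit values round-trip bit-exactly. NA/NaN
#' markers survive the round trip.
#'
#' @param m numeric matrix.
#' @param path output file.
#' @param config_hash optional provenance string.
#' @return `path`, invisibly.
#' @export
write_matrix_txt <- function(m, path, config_hash = NULL) {
  m <- as.matrix(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# netmapr matrix v1",
    paste0("# nrow: ", nrow(m)),
    paste0("# ncol: ", ncol(m)),
    paste0("# config_hash: ", if (is.null(config_hash)) "NA" else config_hash)
  ), con)
  txt <- apply(m, 1, function(r) paste(
    ifelse(is.na(r), "NA", sprintf("%.17g", r)), collapse = "\t"))
  writeLines(txt, con)
  invisible(path)
}

#' @rdname write_matrix_txt
#' @param expected_dim optional c(nrow, ncol); error on mismatch (e.g. when
#'   validating a K x P template matrix).
#' @export
read_matrix_txt <- function(path, expected_dim = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key) sub(paste0("^# ", key, ": "), "",
                                 grep(paste0("^# ", key, ":"), hdr,
                                      value = TRUE)[1])
  nr <- as.integer(get_field("nrow"))
  nc <- as.integer(get_field("ncol"))
  if (is.na(nr) || is.na(nc)) stop("not a netmapr matrix file: ", path)
  body <- lines[!grepl("^#", lines)]
  if (length(body) != nr) {
    stop("truncated matrix file: expected ", nr, " rows, found ",
         length(body))
  }
  m <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    vals <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(vals) != nc) {
      stop("row ", i, " has ", length(vals), " values, expected ", nc)
    }
    m[i, ] <- suppressWarnings(as.numeric(vals))
  }
  if (!is.null(expected_dim) && !all(dim(m) == expected_dim)) {
    stop("dimension mismatch: file is ", nr, " x ", nc, ", expected ",
         expected_dim[1], " x ", expected_dim[2])
  }
  attr(m, "config_hash") <- get_field("config_hash")
  m
}

#' Run configuration
#'
#' A flat, JSON-serializable list of every pipeline knob with the defaults
#' the analyses use. Every stochastic stage has an explicit seed derived
#' from `seed`. Round-trips losslessly through [write_run_config()] /
#' [read_run_config()].
#'
#' @param ... overrides of the defaults.
#' @return a `run_config` list.
#' @export
default_config <- function(...) {
  cfg <- list(
    # cohort
    n_subjects = 12, sessions_per_subject = 2,
    n_vertices = 400, n_parcels = 40, k_true = 6,
    r_w = 0.4, r_b = 0.05, flip_rate = 0.1, boundary_bias = 3,
    n_frames = 240, tr = 0.8, noise_sd = 0.5, p_high = 0.05,
    age_range = c(2, 3), age_effect = 0,
    # censoring
    fd_threshold = 0.2, min_epoch = 3, skip_frames = 5,
    notch_band = c(0.27, 0.5),
    # templates
    k_range = c(2, 12), n_splits = 6, n_replicates = 20,
    stability_replicates = 3, chosen_k_policy = "highest_local_max",
    select_k = FALSE, k = 6,
    # mapping
    exclude_self_parcel = FALSE,
    # consensus
    consensus_thresholds = c(0.35, 0.45, 0.55, 0.65, 0.75),
    # reliability
    n_permutations = 200,
    # behavior
    beta_true = 10, behavior_noise_sd = 5, run_stats = TRUE,
    seed = 1
  )
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "run_config")
}

#' @rdname default_config
#' @param config a `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname default_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_config()
  cfg[names(raw)] <- raw
  cfg
}

#' FNV-1a hash of a configuration (provenance stamp)
#'
#' @param config a `run_config` (or any serializable list).
#' @return 8-hex-digit string embedded in every pipeline output file.
#' @export
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s)) %% 256L
  # 32-bit FNV-1a in double arithmetic (split to keep products < 2^53)
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    h <- (h %/% 256) * 256 + bitwXor(as.integer(h %% 256), as.integer(b))
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * prime) %% 65536) * 65536 + lo * prime) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
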