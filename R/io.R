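# Plain-text serialization. Doubles are written with %.17g so that CSV
# round-trips are bit-exact.

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Write a cFP dataset to tidy CSV (plus JSON sidecar)
#'
#' Columns `colony_id,time_h,cell_count` (one row per colony-time), with
#' ground-truth founder states written only on request. A JSON sidecar
#' (same path, `.json` extension) records the treatment time and
#' metadata.
#'
#' @param dataset a [cfp_dataset()].
#' @param path output CSV path.
#' @param include_founder include the synthetic ground-truth
#'   `founder_state` column (default `FALSE`: labels never leak into
#'   analysis-facing files).
#' @param sidecar write the JSON sidecar, default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_cfp_csv <- function(dataset, path, include_founder = FALSE,
                          sidecar = TRUE) {
  stopifnot(inherits(dataset, "cfp_dataset"))
  rows <- lapply(dataset$traces, function(tr) {
    d <- data.frame(colony_id = tr$colony_id,
                    time_h = fmt_num(tr$times),
                    cell_count = tr$counts)
    if (include_founder) {
      d$founder_state <- tr$founder_state %||% NA_character_
    }
    d
  })
  df <- if (length(rows) > 0L) do.call(rbind, rows) else {
    d <- data.frame(colony_id = character(), time_h = character(),
                    cell_count = integer())
    if (include_founder) d$founder_state <- character()
    d
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (sidecar) {
    meta <- c(list(treatment_time_h = dataset$treatment_time),
              dataset$metadata)
    jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

sidecar_path <- function(path) sub("\\.[^.]+$", ".json", path)

#' Read a cFP dataset written by [write_cfp_csv()]
#'
#' @param path CSV path; the JSON sidecar is read when present,
#'   otherwise `treatment_time` must be given.
#' @param treatment_time fallback treatment time in hours.
#' @return A [cfp_dataset()].
#' @export
read_cfp_csv <- function(path, treatment_time = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  meta <- list()
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
    treatment_time <- treatment_time %||% meta$treatment_time_h
    meta$treatment_time_h <- NULL
  }
  if (is.null(treatment_time)) {
    stop("treatment_time required (no sidecar found)", call. = FALSE)
  }
  treatment_time <- as.numeric(treatment_time)
  traces <- lapply(split(df, factor(df$colony_id,
                                    levels = unique(df$colony_id))),
                   function(d) {
    colony_trace(d$colony_id[1L], as.numeric(d$time_h), d$cell_count,
                 founder_state = if ("founder_state" %in% names(d)) {
                   d$founder_state[1L]
                 } else NULL)
  })
  names(traces) <- NULL
  cfp_dataset(traces, treatment_time = treatment_time, metadata = meta)
}

#' Write DIP-rate distributions to CSV
#'
#' Columns `group,colony_id,dip_rate`.
#'
#' @param dists a [dip_distribution()] or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dip_csv <- function(dists, path) {
  if (inherits(dists, "dip_distribution")) dists <- list(dists)
  df <- do.call(rbind, lapply(dists, function(d) {
    data.frame(group = d$group_label,
               colony_id = d$colony_ids %||%
                 sprintf("c%04d", seq_along(d$dip_rates)),
               dip_rate = fmt_num(d$dip_rates))
  }))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read DIP-rate distributions written by [write_dip_csv()]
#'
#' @param path CSV path.
#' @return A list of [dip_distribution()] objects, one per group.
#' @export
read_dip_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, factor(df$group, levels = unique(df$group))),
         function(d) {
           dip_distribution(as.numeric(d$dip_rate), group_label = d$group[1L],
                            colony_ids = d$colony_id)
         })
}

#' Write a parameter scan to long-format CSV plus JSON manifest
#'
#' @param scan a `scan_grid`.
#' @param path output CSV path; the manifest goes to the `.json` sidecar.
#' @return `path`, invisibly.
#' @export
write_scan_csv <- function(scan, path) {
  stopifnot(inherits(scan, "scan_grid"))
  df <- scan$cells
  for (col in intersect(c("k_div", "k_dth", "k_div1", "k_dth1", "k_div2",
                          "k_dth2", "net_dip", "p_mean", "p_sd"),
                        names(df))) {
    df[[col]] <- fmt_num(df[[col]])
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  manifest <- list(type = scan$type, seed = scan$seed,
                   n_colonies = scan$n_colonies,
                   n_resamples = scan$n_resamples, alpha = scan$alpha,
                   axes = scan$axes,
                   founder_fraction = scan$founder_fraction,
                   mode_ranges = scan$mode_ranges)
  jsonlite::write_json(manifest, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Write / read an ontology DAG as a TSV edge list
#'
#' Columns `child,parent,relation`.
#'
#' @param dag a [term_dag()].
#' @param path TSV path.
#' @return `path` invisibly (writer); a [term_dag()] (reader).
#' @export
write_term_dag_tsv <- function(dag, path) {
  stopifnot(inherits(dag, "term_dag"))
  write.table(dag$edges[, c("child", "parent", "relation")], path,
              sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_term_dag_tsv
#' @param relation_weights weights passed to [term_dag()].
#' @export
read_term_dag_tsv <- function(path,
                              relation_weights = c(is_a = 0.8,
                                                   part_of = 0.6)) {
  edges <- read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  term_dag(edges, relation_weights = relation_weights)
}

#' Write / read gene-to-term annotations as two-column TSV
#'
#' @param annotation data.frame with columns `gene`, `term`.
#' @param path TSV path.
#' @return `path` invisibly (writer); a data.frame (reader).
#' @export
write_annotation_tsv <- function(annotation, path) {
  write.table(annotation[, c("gene", "term")], path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_annotation_tsv
#' @export
read_annotation_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
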