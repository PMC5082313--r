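#' Read and write inclusion (psi) matrices as TSV
#'
#' The on-disk layout is the conventional events-by-samples table: first
#' column the event id, header row the sample ids, cells the inclusion level
#' in `[0,1]` with the literal string `NA` for samples lacking sufficient
#' coverage over the event. In memory the matrix is held long (one row per
#' cell), which is what every modelling function takes.
#'
#' @param path File path.
#' @return `read_psi_table()`: long tibble with columns `event`, `sample`,
#'   `psi` (`NA` = missing).
#' @export
read_psi_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()))
  if (ncol(raw) < 2) {
    abort("psi table needs an event column plus at least one sample column",
          class = "mbnldose_parse_error")
  }
  names(raw)[1] <- "event"
  if (anyDuplicated(raw$event)) {
    abort(sprintf("duplicate event ids: %s",
                  paste(unique(raw$event[duplicated(raw$event)]), collapse = ", ")),
          class = "mbnldose_parse_error")
  }
  long <- tidyr::pivot_longer(raw, -"event", names_to = "sample",
                              values_to = "raw")
  long$psi <- suppressWarnings(as.numeric(long$raw))
  bad <- !is.na(long$raw) & toupper(long$raw) != "NA" &
    (is.na(long$psi) | long$psi < 0 | long$psi > 1)
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf("invalid psi value '%s' at event '%s', sample '%s'",
                  long$raw[i], long$event[i], long$sample[i]),
          class = "mbnldose_parse_error")
  }
  select(long, "event", "sample", "psi")
}

#' @rdname read_psi_table
#' @param psi_long Long tibble (`event`, `sample`, `psi`).
#' @export
write_psi_table <- function(psi_long, path) {
  wide <- psi_long |>
    select("event", "sample", "psi") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "psi")
  readr::write_tsv(wide, path, na = "NA")
  invisible(path)
}

#' Read a dose-series TSV
#'
#' Expected columns: `dose` and/or `log_conc` (or `conc`), `event`, `psi`,
#' optional `replicate` and `mbnl_rel`. When only a raw concentration is
#' present it is log10-transformed into `log_conc`.
#'
#' @param path File path.
#' @return Tibble ready for [fit_dose_response()] (after filtering to one
#'   event).
#' @export
read_dose_series <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols())
  if (!"log_conc" %in% names(d)) {
    src <- intersect(c("mbnl_rel", "conc"), names(d))
    if (length(src) == 0) {
      abort("dose series needs a log_conc, mbnl_rel or conc column",
            class = "mbnldose_parse_error")
    }
    d$log_conc <- log10(d[[src[1]]])
  }
  d
}

#' Write fitted curves as JSON keyed by event
#'
#' @param curves Tibble with columns `event`, `psi_min`, `psi_max`, `ec50`,
#'   `slope` and optionally `sigma`, or a named list of `dose_fit` objects.
#' @param path Output path.
#' @export
write_curves_json <- function(curves, path) {
  if (is.list(curves) && !is.data.frame(curves) &&
      all(purrr::map_lgl(curves, inherits, "dose_fit"))) {
    curves <- purrr::imap_dfr(curves, function(f, nm) {
      p <- f$params
      tibble(event = nm, psi_min = p$psi_min, psi_max = p$psi_max,
             ec50 = p$ec50, slope = p$slope, sigma = p$sigma,
             r_squared = f$r_squared)
    })
  }
  keyed <- setNames(
    purrr::map(seq_len(nrow(curves)),
               function(i) as.list(select(curves[i, ], -"event"))),
    curves$event)
  jsonlite::write_json(keyed, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_curves_json
#' @export
read_curves_json <- function(path) {
  keyed <- jsonlite::read_json(path, simplifyVector = TRUE)
  purrr::imap_dfr(keyed, function(p, nm) {
    as_tibble(p) |> mutate(event = nm, .before = 1)
  })
}

#' Write flank sequences as FASTA
#'
#' Record names encode the event, region and any planted motif offsets
#' (`event|region|planted=p1,p2,...`), so a scan of the file can be checked
#' against the generator's truth.
#'
#' @param regions Tibble from [simulate_exon_regions()].
#' @param path Output path.
#' @export
write_flanks_fasta <- function(regions, path) {
  ids <- sprintf("%s|%s|planted=%s", regions$event, regions$region,
                 purrr::map_chr(regions$planted %||%
                                  rep(list(integer(0)), nrow(regions)),
                                paste, collapse = ","))
  seqs <- Biostrings::DNAStringSet(regions$seq)
  names(seqs) <- ids
  Biostrings::writeXStringSet(seqs, path, width = 80)
  invisible(path)
}

#' @rdname write_flanks_fasta
#' @export
read_flanks_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  meta <- stringr::str_split_fixed(names(seqs), stringr::fixed("|"), 3)
  planted <- purrr::map(meta[, 3], function(x) {
    x <- sub("^planted=", "", x)
    if (nchar(x) == 0) integer(0) else as.integer(strsplit(x, ",")[[1]])
  })
  tibble(event = meta[, 1], region = meta[, 2],
         seq = unname(as.character(seqs)), planted = planted)
}

#' Write event coordinates as BED
#'
#' BED is 0-based half-open, matching the package's internal convention.
#'
#' @param events Tibble with columns `chrom`, `start`, `end`, `event`, and
#'   optionally `strand`.
#' @param path Output path.
#' @export
write_events_bed <- function(events, path) {
  bed <- tibble(
    chrom = events$chrom, start = events$start, end = events$end,
    name = events$event, score = 0,
    strand = events$strand %||% rep(".", nrow(events)))
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
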