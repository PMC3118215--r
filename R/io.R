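#' Read gene models
#'
#' Parses refFlat-style TSV (geneName, name, chrom, strand, txStart, txEnd, ...)
#' or BED12. Both dialects are 0-based half-open, matching the internal
#' convention. The transcription start site is strand-aware: `tx_start` on the
#' plus strand, `tx_end - 1` on the minus strand.
#'
#' @param path File path.
#' @param format `"refflat"` or `"bed12"`.
#' @return Tibble with columns `gene_id`, `name`, `chrom`, `strand`,
#'   `tx_start`, `tx_end`, `tss`, sorted by (`chrom`, `tx_start`).
#' @export
read_gene_models <- function(path, format = c("refflat", "bed12")) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(gene_id = character(), name = character(), chrom = character(),
                  strand = character(), tx_start = numeric(), tx_end = numeric(),
                  tss = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  parse_row <- function(f, i) {
    if (format == "refflat") {
      if (length(f) < 6) abort(sprintf("line %d: refFlat needs >= 6 fields", i))
      list(name = f[1], gene_id = f[2], chrom = f[3], strand = f[4],
           tx_start = suppressWarnings(as.numeric(f[5])),
           tx_end = suppressWarnings(as.numeric(f[6])))
    } else {
      if (length(f) < 6) abort(sprintf("line %d: BED12 needs >= 6 fields", i))
      list(name = f[4], gene_id = f[4], chrom = f[1], strand = f[6],
           tx_start = suppressWarnings(as.numeric(f[2])),
           tx_end = suppressWarnings(as.numeric(f[3])))
    }
  }
  rows <- map2(fields, seq_along(fields), parse_row)
  out <- tibble(
    gene_id = map_chr(rows, "gene_id"),
    name = map_chr(rows, "name"),
    chrom = map_chr(rows, "chrom"),
    strand = map_chr(rows, "strand"),
    tx_start = map_dbl(rows, "tx_start"),
    tx_end = map_dbl(rows, "tx_end")
  )
  bad <- which(is.na(out$tx_start) | is.na(out$tx_end) | out$tx_start >= out$tx_end)
  if (length(bad)) abort(sprintf("line %d: malformed gene coordinates", bad[1]))
  badstr <- which(!out$strand %in% c("+", "-"))
  if (length(badstr)) {
    abort(sprintf("line %d: unknown strand symbol '%s'", badstr[1], out$strand[badstr[1]]))
  }
  out |>
    mutate(tss = if_else(.data$strand == "+", .data$tx_start, .data$tx_end - 1)) |>
    arrange(.data$chrom, .data$tx_start)
}

#' Read CpG islands
#'
#' Parses BED (chrom, start, end, \[name\]) or UCSC cpgIslandExt-style TSV
#' (optionally with a leading `bin` column, then chrom, chromStart, chromEnd,
#' name, ...). Both are 0-based half-open.
#'
#' @param path File path.
#' @param format `"bed"` or `"cpgislandext"`.
#' @return Tibble with `id`, `chrom`, `start`, `end`, sorted.
#' @export
read_cpg_islands <- function(path, format = c("bed", "cpgislandext")) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(id = character(), chrom = character(), start = numeric(), end = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  parse_row <- function(f, i) {
    if (format == "cpgislandext" && length(f) >= 4 &&
        !is.na(suppressWarnings(as.numeric(f[1]))) &&
        is.na(suppressWarnings(as.numeric(f[2])))) {
      f <- f[-1]  # leading UCSC bin column
    }
    if (length(f) < 3) abort(sprintf("line %d: need >= 3 fields", i))
    st <- suppressWarnings(as.numeric(f[2])); en <- suppressWarnings(as.numeric(f[3]))
    if (is.na(st) || is.na(en) || st >= en) abort(sprintf("line %d: malformed coordinates", i))
    list(chrom = f[1], start = st, end = en,
         id = if (length(f) >= 4) f[4] else sprintf("cpgi_%d", i))
  }
  rows <- map2(fields, seq_along(fields), parse_row)
  tibble(
    id = map_chr(rows, "id"),
    chrom = map_chr(rows, "chrom"),
    start = map_dbl(rows, "start"),
    end = map_dbl(rows, "end")
  ) |> arrange(.data$chrom, .data$start)
}

#' Read a probe layout
#'
#' TSV with columns `chrom`, `start`, `end`, `probe_id` (header optional, any
#' column order when a header is present).
#'
#' @param path File path.
#' @return Tibble `probe_id`, `chrom`, `start`, `end`, `center`, sorted by
#'   (`chrom`, `start`). Probe ids must be unique.
#' @export
read_probe_layout <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("probe_id", first)
  df <- readr::read_tsv(path, col_names = has_header,
                        show_col_types = FALSE, progress = FALSE)
  if (!has_header) names(df) <- c("chrom", "start", "end", "probe_id")[seq_along(df)]
  as_probe_layout(df)
}

#' Normalise a probe table into a layout
#'
#' @param df Data frame with `probe_id`, `chrom`, `start`, `end`.
#' @return Sorted layout tibble with derived `center` (interval midpoint).
#' @export
as_probe_layout <- function(df) {
  need <- c("probe_id", "chrom", "start", "end")
  if (!all(need %in% names(df))) abort("layout needs columns probe_id, chrom, start, end")
  assert_intervals(df, "probe layout")
  if (anyDuplicated(df$probe_id)) abort("duplicate probe_id in layout")
  df |>
    as_tibble() |>
    mutate(probe_id = as.character(.data$probe_id),
           center = (.data$start + .data$end) / 2) |>
    select(all_of(c("probe_id", "chrom", "start", "end", "center"))) |>
    arrange(.data$chrom, .data$start)
}

#' Read one replicate's signal track
#'
#' TSV with columns `probe_id`, `log2_ratio`.
#'
#' @param path File path.
#' @param tissue,stage,replicate Sample labels attached as columns.
#' @return Signal tibble (`tissue`, `stage`, `replicate`, `probe_id`,
#'   `log2_ratio`), unscaled.
#' @export
read_signal_track <- function(path, tissue = NA_character_, stage = NA_character_,
                              replicate = NA_integer_) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("probe_id", "log2_ratio") %in% names(df))) {
    abort("signal TSV needs columns probe_id, log2_ratio")
  }
  if (any(!is.finite(df$log2_ratio))) abort("non-finite log2_ratio in signal track")
  tibble(tissue = tissue, stage = stage, replicate = as.integer(replicate),
         probe_id = as.character(df$probe_id), log2_ratio = df$log2_ratio)
}

#' Read a NimbleGen-dialect GFF signal or P-score file
#'
#' GFF2-style rows whose score column carries the per-probe value and whose
#' attribute/group column carries the probe id. GFF coordinates are
#' 1-based inclusive and are converted to the internal 0-based half-open form.
#'
#' @param path File path.
#' @return Tibble `probe_id`, `chrom`, `start`, `end`, `score`.
#' @export
read_nimblegen_gff <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(probe_id = character(), chrom = character(),
                  start = numeric(), end = numeric(), score = numeric()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 9)) abort(sprintf("line %d: GFF needs 9 fields", which(nf < 9)[1]))
  tibble(
    probe_id = sub("^.*?([A-Za-z0-9_.:-]+);?\\s*$", "\\1",
                   sub(".*=", "", map_chr(f, 9))),
    chrom = map_chr(f, 1),
    start = as.numeric(map_chr(f, 4)) - 1,
    end = as.numeric(map_chr(f, 5)),
    score = as.numeric(map_chr(f, 6))
  )
}

#' Write per-probe P scores as NimbleGen-style GFF
#'
#' @param pscores P-score tibble (`probe_id`, `pscore`).
#' @param layout Probe layout.
#' @param path Output path.
#' @param source Source tag for column 2.
#' @return `path`, invisibly.
#' @export
write_pscore_gff <- function(pscores, layout, path, source = "medipdmr") {
  df <- if (all(c("chrom", "start", "end") %in% names(pscores))) pscores else
    left_join(pscores, layout, by = "probe_id")
  lines <- sprintf("%s\t%s\tpscore\t%d\t%d\t%.6g\t.\t.\tprobe_id=%s",
                   df$chrom, source, as.integer(df$start + 1), as.integer(df$end),
                   df$pscore, df$probe_id)
  writeLines(lines, path)
  invisible(path)
}

#' Write intervals as BED
#'
#' BED3 when `name`/`score` are absent, BED6 otherwise (strand `.`). Scores are
#' rounded to integers per the BED convention.
#'
#' @param x Interval table; optional columns `name` and `score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  assert_intervals(x)
  if (any(c("name", "score") %in% names(x))) {
    nm <- if ("name" %in% names(x)) x$name else "."
    sc <- round(if ("score" %in% names(x)) x$score else 0)
    lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.", x$chrom, as.integer(x$start),
                     as.integer(x$end), nm, as.integer(sc))
  } else {
    lines <- sprintf("%s\t%d\t%d", x$chrom, as.integer(x$start), as.integer(x$end))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED3/BED6 file
#'
#' @param path File path.
#' @return Interval tibble; `name` and `score` columns when present in the file.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- min(lengths(f))
  out <- tibble(chrom = map_chr(f, 1),
                start = as.numeric(map_chr(f, 2)),
                end = as.numeric(map_chr(f, 3)))
  if (nf >= 4) out$name <- map_chr(f, 4)
  if (nf >= 5) out$score <- as.numeric(map_chr(f, 5))
  assert_intervals(out, sprintf("BED file %s", path))
  out
}
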