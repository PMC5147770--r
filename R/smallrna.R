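#' Quality-filter small-RNA reads
#'
#' Retains reads with mean Phred quality at or above `min_mean_q` and no
#' ambiguous `N` base. Input order is preserved.
#'
#' @param reads tibble with `id`, `sequence`, `quality` (Phred+33 string),
#'   as from [read_fastq()].
#' @param min_mean_q minimum mean Phred score (default 20).
#' @return the filtered read tibble.
#' @export
filter_quality <- function(reads, min_mean_q = 20) {
  stopifnot(all(c("id", "sequence", "quality") %in% names(reads)))
  bad_len <- nchar(reads$sequence) != nchar(reads$quality)
  if (any(bad_len)) {
    stop("malformed FASTQ record (sequence/quality length mismatch): ",
         reads$id[which(bad_len)[1]])
  }
  if (nrow(reads) == 0) return(reads)
  keep <- !grepl("N", reads$sequence, fixed = TRUE) &
    mean_phred(reads$quality) >= min_mean_q
  reads[keep, , drop = FALSE]
}

#' Trim a 3' adapter from reads
#'
#' Finds the leftmost exact occurrence of an adapter prefix (at least
#' `min_overlap` nt long) and removes it together with everything 3' of it.
#' Reads with no adapter hit are kept whole; reads shorter than `min_keep`
#' after trimming are discarded.
#'
#' @param reads read tibble.
#' @param adapter 3' adapter sequence.
#' @param min_overlap minimum adapter prefix length to trigger trimming
#'   (default 8).
#' @param min_keep minimum trimmed read length retained (default 15).
#' @return read tibble with trimmed `sequence`/`quality`.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 8, min_keep = 15) {
  stopifnot(nchar(adapter) >= min_overlap)
  if (nrow(reads) == 0) return(reads)
  probe <- toupper(substr(adapter, 1, min_overlap))
  pos <- regexpr(probe, reads$sequence, fixed = TRUE)
  cut <- ifelse(pos > 0, pos - 1L, nchar(reads$sequence))
  out <- reads
  out$sequence <- substr(out$sequence, 1, cut)
  out$quality <- substr(out$quality, 1, cut)
  out[nchar(out$sequence) >= min_keep, , drop = FALSE]
}

#' Collapse reads to unique tags with per-library counts
#'
#' One row per distinct sequence; counts split by library. The sum of all
#' counts equals the number of input reads.
#'
#' @param reads read tibble with an additional `library` column, or a named
#'   list of read tibbles (names = library ids).
#' @return tag tibble: `tag` (sequence), one integer count column per
#'   library, and `total`.
#' @export
collapse_tags <- function(reads) {
  if (is.data.frame(reads)) {
    stopifnot("library" %in% names(reads))
    df <- reads
  } else {
    df <- purrr::imap_dfr(reads, ~dplyr::mutate(.x, library = .y))
  }
  if (nrow(df) == 0) {
    return(tibble(tag = character(), total = integer()))
  }
  libs <- unique(df$library)
  wide <- df %>%
    dplyr::count(.data$sequence, .data$library) %>%
    tidyr::pivot_wider(names_from = "library", values_from = "n",
                       values_fill = 0L) %>%
    dplyr::rename(tag = "sequence")
  missing <- setdiff(libs, names(wide))
  for (m in missing) wide[[m]] <- 0L
  wide$total <- as.integer(rowSums(wide[, libs, drop = FALSE]))
  dplyr::arrange(wide[, c("tag", libs, "total")], .data$tag)
}

#' Map tags to a genome by exact matching
#'
#' Reports every exact occurrence of each tag on both strands. A minus-strand
#' hit at `start` means the reverse complement of the tag equals the genome
#' substring starting there. Hits are ordered by (tag, chromosome, start,
#' strand); starts are 0-based.
#'
#' @param tags tag tibble from [collapse_tags()] (or any tibble with a `tag`
#'   column).
#' @param genome named character vector of chromosome sequences.
#' @return tibble `tag`, `chrom`, `start` (0-based), `strand`; tags with no
#'   occurrence are absent (see `attr(,"unmapped")` for their sequences).
#' @export
map_exact <- function(tags, genome) {
  stopifnot("tag" %in% names(tags), length(genome) > 0, !is.null(names(genome)))
  subjects <- DNAStringSet(toupper(genome))
  hit_rows <- purrr::map_dfr(unique(tags$tag), function(tg) {
    if (grepl("[^ACGT]", tg)) return(NULL)
    pat <- DNAStringSet(tg)[[1]]
    rcpat <- reverseComplement(pat)
    purrr::map_dfr(seq_along(subjects), function(ci) {
      subj <- subjects[[ci]]
      if (length(pat) > length(subj)) return(NULL)
      fw <- matchPattern(pat, subj)
      rv <- matchPattern(rcpat, subj)
      res <- list()
      if (length(fw) > 0) {
        res$fw <- tibble(tag = tg, chrom = names(genome)[ci],
                         start = BiocGenerics::start(fw) - 1L, strand = "+")
      }
      if (length(rv) > 0) {
        res$rv <- tibble(tag = tg, chrom = names(genome)[ci],
                         start = BiocGenerics::start(rv) - 1L, strand = "-")
      }
      dplyr::bind_rows(res)
    })
  })
  if (nrow(hit_rows) == 0) {
    hit_rows <- tibble(tag = character(), chrom = character(),
                       start = integer(), strand = character())
  }
  hit_rows <- dplyr::arrange(hit_rows, .data$tag, .data$chrom, .data$start,
                             .data$strand)
  attr(hit_rows, "unmapped") <- setdiff(tags$tag, hit_rows$tag)
  hit_rows
}

#' Remove tags overlapping structural RNAs
#'
#' Any tag with at least one genome hit overlapping (by one or more nt,
#' either strand) an annotated tRNA, rRNA, snRNA or snoRNA feature is removed
#' entirely from the tag set.
#'
#' @param tags tag tibble.
#' @param hits hit tibble from [map_exact()].
#' @param annotations tibble with `chrom`, `start` (0-based), `end`
#'   (half-open), `class`.
#' @param classes feature classes treated as structural.
#' @return filtered tag tibble.
#' @export
exclude_structural <- function(tags, hits, annotations,
                               classes = c("tRNA", "rRNA", "snRNA",
                                           "snoRNA")) {
  stopifnot(all(c("chrom", "start", "end", "class") %in% names(annotations)))
  unknown <- setdiff(unique(annotations$class),
                     c(classes, "miRNA", "miRNA_primary_transcript", "gene"))
  if (length(unknown) > 0) {
    warning("ignoring unknown annotation classes: ",
            paste(unknown, collapse = ", "))
  }
  ann <- annotations[annotations$class %in% classes, , drop = FALSE]
  if (nrow(ann) == 0 || nrow(hits) == 0) return(tags)
  h <- dplyr::mutate(hits, end = .data$start + nchar(.data$tag))
  bad <- h %>%
    dplyr::inner_join(ann, by = "chrom", suffix = c("", ".ann"),
                      relationship = "many-to-many") %>%
    dplyr::filter(.data$start < .data$end.ann, .data$end > .data$start.ann) %>%
    dplyr::pull(.data$tag) %>%
    unique()
  tags[!tags$tag %in% bad, , drop = FALSE]
}

#' Select tags by sequence length
#'
#' Inclusive bounds; defaults retain the 18-28 nt small-RNA range.
#'
#' @param tags tag tibble.
#' @param min_len,max_len inclusive length bounds (defaults 18 and 28).
#' @return filtered tag tibble.
#' @export
length_filter <- function(tags, min_len = 18, max_len = 28) {
  if (min_len > max_len) stop("min_len exceeds max_len")
  len <- nchar(tags$tag)
  tags[len >= min_len & len <= max_len, , drop = FALSE]
}

#' Normalize tag counts to CP10M
#'
#' Count per 10 million mapped reads: `count * 1e7 / mapped_total`.
#'
#' @param tags tag tibble with per-library count columns.
#' @param mapped_total named numeric vector, mapped-read total per library.
#' @return tibble `tag` plus one CP10M column per library.
#' @export
normalize_cp10m <- function(tags, mapped_total) {
  libs <- names(mapped_total)
  stopifnot(all(libs %in% names(tags)))
  if (any(mapped_total == 0)) {
    stop("mapped_total is zero for library: ",
         paste(libs[mapped_total == 0], collapse = ", "))
  }
  out <- tags[, c("tag", libs), drop = FALSE]
  for (l in libs) out[[l]] <- out[[l]] * 1e7 / mapped_total[[l]]
  out
}

#' Length by 5'-nucleotide expression profile
#'
#' Sums CP10M into (length, 5'-nucleotide) cells over the 18-28 nt range —
#' the standard small-RNA composition profile (U-biased 21-mers indicate
#' miRNAs, A-biased 24-mers heterochromatic siRNAs).
#'
#' @param cp10m tibble from [normalize_cp10m()].
#' @param min_len,max_len length range of the profile.
#' @return long tibble `library`, `length`, `first_nt` (RNA alphabet),
#'   `cp10m`; all (length, nt) cells present, zero-filled.
#' @export
length_5p_profile <- function(cp10m, min_len = 18, max_len = 28) {
  libs <- setdiff(names(cp10m), "tag")
  grid <- tidyr::expand_grid(
    library = libs, length = min_len:max_len, first_nt = c("A", "C", "G", "U")
  )
  if (nrow(cp10m) == 0) {
    return(dplyr::mutate(grid, cp10m = 0))
  }
  long <- cp10m %>%
    dplyr::mutate(length = nchar(.data$tag),
                  first_nt = dna_to_rna(substr(.data$tag, 1, 1))) %>%
    tidyr::pivot_longer(dplyr::all_of(libs), names_to = "library",
                        values_to = "value") %>%
    dplyr::group_by(.data$library, .data$length, .data$first_nt) %>%
    dplyr::summarise(cp10m = sum(.data$value), .groups = "drop")
  grid %>%
    dplyr::left_join(long, by = c("library", "length", "first_nt")) %>%
    dplyr::mutate(cp10m = dplyr::coalesce(.data$cp10m, 0))
}

#' Run the small-RNA preprocessing stages in order
#'
#' Quality filter, adapter trim, collapse, exact mapping, structural-RNA
#' exclusion, 18-28 nt selection, CP10M normalization — with per-stage
#' attrition counts.
#'
#' @param read_sets named list of read tibbles (one per library).
#' @param genome named character vector.
#' @param annotations annotation tibble (see [exclude_structural()]).
#' @param adapter 3' adapter sequence.
#' @param min_mean_q,min_len,max_len stage thresholds.
#' @return list with `tags` (filtered tag tibble), `hits`, `cp10m`,
#'   `mapped_total`, and `stats` (per-library attrition tibble).
#' @export
process_small_rna <- function(read_sets, genome, annotations, adapter,
                              min_mean_q = 20, min_len = 18, max_len = 28) {
  qc <- purrr::map(read_sets, filter_quality, min_mean_q = min_mean_q)
  trimmed <- purrr::map(qc, trim_adapter, adapter = adapter)
  tags <- collapse_tags(trimmed)
  hits <- map_exact(tags, genome)
  libs <- names(read_sets)
  mapped_tags <- tags[tags$tag %in% unique(hits$tag), , drop = FALSE]
  no_struct <- exclude_structural(mapped_tags, hits, annotations)
  selected <- length_filter(no_struct, min_len, max_len)
  mapped_total <- vapply(libs, function(l) sum(mapped_tags[[l]]), numeric(1))
  cp10m <- normalize_cp10m(selected, mapped_total)
  stats <- tibble(
    library = libs,
    total_raw = vapply(read_sets, nrow, integer(1)),
    total_after_qc = vapply(qc, nrow, integer(1)),
    total_trimmed = vapply(trimmed, nrow, integer(1)),
    mapped = vapply(libs, function(l) sum(mapped_tags[[l]]), numeric(1)),
    structural_removed = vapply(
      libs, function(l) sum(mapped_tags[[l]]) - sum(no_struct[[l]]),
      numeric(1)),
    selected_18_28 = vapply(libs, function(l) sum(selected[[l]]), numeric(1))
  )
  list(tags = selected, hits = hits[hits$tag %in% selected$tag, , drop = FALSE],
       cp10m = cp10m, mapped_total = mapped_total, stats = stats)
}
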