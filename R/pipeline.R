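#' Pipeline run configuration
#'
#' Collects every stage threshold in one place. Defaults are the
#' conventional values of this analysis: seed support 50 reads, duplex
#' mismatch ratio 0.3, 18-28 nt tag selection, 15 nt refold margin,
#' 100-500 nt window extensions, target penalty ceiling 6 with
#' high-confidence 5, miRNA fold change 1.5, gene fold change 2,
#' alpha 0.05 after BH, replicate-correlation FPKM floor 0.5.
#'
#' @param synth a [synth_config()] describing the simulated inputs.
#' @param min_reads,max_ratio,min_len,max_len,margin,extensions discovery
#'   thresholds.
#' @param max_score,hc_score target-prediction thresholds.
#' @param mirna_fc,gene_fc,alpha,min_expr,min_fpkm differential-expression
#'   thresholds.
#' @param min_mean_q read quality floor.
#' @return a `run_config` list.
#' @export
run_config <- function(synth = synth_config(),
                       min_reads = 50, max_ratio = 0.3,
                       min_len = 18, max_len = 28, margin = 15,
                       extensions = seq(100, 500, 100),
                       max_score = 6, hc_score = 5,
                       mirna_fc = 1.5, gene_fc = 2, alpha = 0.05,
                       min_expr = 1, min_fpkm = 0.5, min_mean_q = 20) {
  cfg <- list(synth = synth, min_reads = min_reads, max_ratio = max_ratio,
              min_len = min_len, max_len = max_len, margin = margin,
              extensions = extensions, max_score = max_score,
              hc_score = hc_score, mirna_fc = mirna_fc, gene_fc = gene_fc,
              alpha = alpha, min_expr = min_expr, min_fpkm = min_fpkm,
              min_mean_q = min_mean_q)
  class(cfg) <- "run_config"
  cfg
}

#' Serialize / parse a run configuration
#'
#' @param config a `run_config`.
#' @param path JSON file path.
#' @return `write_run_config` returns `path`; `read_run_config` the parsed
#'   `run_config` (round-trip identical).
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$synth <- unclass(x$synth)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sy <- x$synth
  sy$libraries <- as_tibble(sy$libraries)
  sy$effect_table <- as_tibble(sy$effect_table)
  if (nrow(sy$effect_table) == 0) sy$effect_table <- NULL
  cfg <- do.call(synth_config, sy[setdiff(names(sy), character(0))])
  x$synth <- NULL
  x$extensions <- as.numeric(x$extensions)
  do.call(run_config, c(list(synth = cfg), x))
}

#' Run the full synthetic pipeline
#'
#' simulate -> small-RNA processing -> miRNA discovery -> target scanning
#' -> differential expression (per genotype x tissue, ethylene vs air) ->
#' set integration. Every stage result is returned; when `out_dir` is
#' given, stage outputs and a manifest are also written there.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @return list with `truth`, `genome`, `processed`, `length_profile`,
#'   `replicate_qc` (log2-FPKM replicate correlations), `candidates`,
#'   `predictions`, `mirna_diff`, `gene_diff` (named by `genotype_tissue`),
#'   `venn`, `dependence`, `pairs`, and `manifest`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  sy <- config$synth

  gb <- build_genome(sy)
  reads <- simulate_small_rna_libraries(gb$truth, sy, gb$genome)
  tx <- simulate_transcriptome_counts(gb$truth, sy)
  ann <- truth_annotations(gb$truth)

  processed <- process_small_rna(reads, gb$genome, ann, sy$adapter,
                                 min_mean_q = config$min_mean_q,
                                 min_len = config$min_len,
                                 max_len = config$max_len)

  known <- setNames(gb$truth$mirna_loci$mature, gb$truth$mirna_loci$locus)
  candidates <- discover_mirnas(processed, gb$genome, known,
                                min_reads = config$min_reads,
                                max_ratio = config$max_ratio,
                                margin = config$margin,
                                extensions = config$extensions)
  candidates$id <- dplyr::coalesce(candidates$known_match,
                                   paste0("novel_", candidates$family))

  ## one sequence per candidate id; prefer the arm that directly matched a
  ## known mature over family-inherited labels (the star arm inherits the
  ## family name but is not the guide strand)
  ord <- order(!candidates$direct_match)
  mirnas <- setNames(candidates$mature[ord], candidates$id[ord])
  mirnas <- mirnas[!duplicated(names(mirnas))]
  predictions <- scan_transcriptome(mirnas, tx$transcripts,
                                    max_score = config$max_score,
                                    hc_score = config$hc_score)

  libs <- sy$libraries
  design <- dplyr::distinct(libs, .data$genotype, .data$tissue)
  mirna_counts <- dplyr::bind_cols(
    tibble(feature = names(mirnas)),
    processed$tags[match(unname(mirnas), processed$tags$tag),
                   libs$library, drop = FALSE])
  mirna_diff <- list(); gene_diff <- list()
  for (d in seq_len(nrow(design))) {
    gt <- design$genotype[d]; ti <- design$tissue[d]
    key <- paste(gt, ti, sep = "_")
    pick <- function(tr) libs$library[libs$genotype == gt &
                                        libs$tissue == ti &
                                        libs$treatment == tr]
    contrast <- list(cond1 = pick("ethylene"), cond2 = pick("air"))
    mirna_diff[[key]] <- diff_mirna(mirna_counts, contrast,
                                    min_fc = config$mirna_fc,
                                    alpha = config$alpha,
                                    totals = processed$mapped_total)
    gene_diff[[key]] <- diff_gene(tx$counts, tx$lengths, contrast,
                                  min_fc = config$gene_fc,
                                  alpha = config$alpha,
                                  min_expr = config$min_expr,
                                  totals = tx$totals)
  }

  fpkm <- compute_fpkm(tx$counts, tx$lengths, tx$totals)
  replicate_qc <- replicate_correlation(fpkm, min_fpkm = config$min_fpkm)

  diff_set <- function(calls) calls$feature[calls$direction != "ns"]
  venn <- list(
    mirna_root = venn_counts(diff_set(mirna_diff$Col0_root),
                             diff_set(mirna_diff$cbp20_root)),
    mirna_shoot = venn_counts(diff_set(mirna_diff$Col0_shoot),
                              diff_set(mirna_diff$cbp20_shoot)),
    gene_root = venn_counts(diff_set(gene_diff$Col0_root),
                            diff_set(gene_diff$cbp20_root)))
  root_specific <- tissue_specific(diff_set(mirna_diff$Col0_root),
                                   diff_set(mirna_diff$Col0_shoot))
  dep_mirna <- cbp20_dependent(mirna_diff$Col0_root, mirna_diff$cbp20_root)
  dep_gene <- cbp20_dependent(gene_diff$Col0_root, gene_diff$cbp20_root)
  pairs <- anticorrelated_pairs(
    mirna_diff$Col0_root, gene_diff$Col0_root, predictions,
    dependence = list(mirna = dep_mirna$dependent, gene = dep_gene$dependent))

  result <- list(truth = gb$truth, genome = gb$genome, reads = reads,
                 transcriptome = tx, processed = processed,
                 length_profile = length_5p_profile(processed$cp10m),
                 replicate_qc = replicate_qc,
                 candidates = candidates, predictions = predictions,
                 mirna_diff = mirna_diff, gene_diff = gene_diff,
                 venn = venn, root_specific = root_specific,
                 dependence = list(mirna = dep_mirna, gene = dep_gene),
                 pairs = pairs)
  if (!is.null(out_dir)) {
    result$manifest <- write_run_outputs(result, config, out_dir)
  }
  result
}

write_run_outputs <- function(result, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_fasta(result$genome, p("genome.fasta"))
  write_annotations(truth_annotations(result$truth), p("annotations.gff3"))
  for (lib in names(result$reads)) {
    write_fastq(result$reads[[lib]], p(paste0(lib, ".fastq")))
  }
  write_fasta(result$transcriptome$transcripts, p("transcripts.fasta"))
  write_tsv_plain(result$processed$tags, p("tags.tsv"))
  write_tsv_plain(result$candidates, p("candidates.tsv"))
  write_tsv_plain(result$predictions, p("predictions.tsv"))
  for (key in names(result$mirna_diff)) {
    write_tsv_plain(result$mirna_diff[[key]],
                    p(paste0("diff_mirna_", key, ".tsv")))
    write_tsv_plain(result$gene_diff[[key]],
                    p(paste0("diff_gene_", key, ".tsv")))
  }
  write_tsv_plain(result$pairs, p("pairs.tsv"))
  jsonlite::write_json(
    list(mirna_root = result$venn$mirna_root$counts,
         gene_root = result$venn$gene_root$counts,
         root_specific = result$root_specific),
    p("venn.json"), auto_unbox = FALSE)
  id_by_tag <- setNames(result$candidates$id, result$candidates$mature)
  expr <- result$processed$cp10m[result$processed$cp10m$tag %in%
                                   names(id_by_tag), ]
  expr$tag <- unname(id_by_tag[expr$tag])
  heat <- export_heatmap_matrix(result$mirna_diff$Col0_root, expr)
  write_tsv_plain(heat, p("heatmap_mirna_root.tsv"))
  cfg_path <- p("config.json")
  write_run_config(config, cfg_path)
  manifest <- list(
    config_md5 = unname(tools::md5sum(cfg_path)),
    stages = list(
      libraries = length(result$reads),
      tags = nrow(result$processed$tags),
      candidates = nrow(result$candidates),
      predictions = nrow(result$predictions),
      pairs = nrow(result$pairs)),
    files = sort(list.files(out_dir)))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  manifest
}

#' Write annotations as GFF3
#'
#' Converts the internal 0-based half-open annotation tibble to 1-based
#' inclusive GFF3.
#'
#' @param ann annotation tibble (`chrom`, `start`, `end`, `strand`,
#'   `class`, `id`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tethysmall\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                     ann$chrom, ann$class, ann$start + 1L, ann$end,
                     ann$strand, ann$id))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GFF3 annotation file
#'
#' Uses `rtracklayer` when available, else a minimal tab parser; returns
#' the internal 0-based half-open tibble.
#'
#' @param path GFF3 file.
#' @return annotation tibble.
#' @export
read_annotations <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "gff3")
    return(tibble(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = BiocGenerics::start(gr) - 1L,
      end = BiocGenerics::end(gr),
      strand = as.character(BiocGenerics::strand(gr)),
      class = as.character(gr$type),
      id = as.character(gr$ID)))
  }
  raw <- utils::read.table(path, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  tibble(chrom = raw$V1, start = raw$V4 - 1L, end = raw$V5,
         strand = raw$V7, class = raw$V3,
         id = sub("^ID=", "", raw$V9))
}
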