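#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the simulator: genome geometry, planted miRNA
#' hairpin loci, structural-RNA loci, the library design (genotype x tissue
#' x treatment x replicate), sequencing depth, per-condition fold effects
#' and the RNG seed. Defaults emulate the experimental design the pipeline
#' is aimed at: two genotypes (Col-0, cbp20) by two tissues (root, shoot)
#' by two treatments (air, ethylene) by two replicates.
#'
#' @param genome_length genome size in nt.
#' @param n_mirna_loci number of planted miRNA hairpin loci.
#' @param n_structural_loci number of planted structural-RNA loci.
#' @param mature_length mature miRNA length in nt (default 21).
#' @param loop_length hairpin loop length in nt (default 15).
#' @param star_mismatches substitutions planted in the star arm per locus
#'   (scalar or vector of length `n_mirna_loci`).
#' @param libraries tibble with `genotype`, `tissue`, `treatment`,
#'   `replicate`; default is the full 2x2x2x2 design.
#' @param base_depth reads per library.
#' @param effect_table tibble `locus`, `genotype`, `tissue`, `treatment`,
#'   `fold`: per-condition abundance fold change of a planted miRNA locus
#'   relative to baseline. Missing combinations mean fold 1.
#' @param adapter 3' sequencing adapter.
#' @param read_length raw read length in nt.
#' @param mature_weight relative abundance weight of each mature tag.
#' @param star_fraction star abundance as a fraction of mature (default 0.1).
#' @param n_background_tags random genome-derived background tags.
#' @param background_weight relative weight of each background tag.
#' @param n_struct_frags structural-RNA fragments sampled per structural
#'   locus.
#' @param struct_weight relative weight of each structural fragment.
#' @param low_quality_fraction fraction of reads emitted with uniformly low
#'   quality (Phred 2).
#' @param target_scores intended penalty scores of planted target sites,
#'   recycled over miRNA loci.
#' @param target_fold fold by which a hosted target transcript goes down
#'   in conditions where its miRNA goes up (default 2.5: comfortably past
#'   the 2-fold calling threshold, which pseudo-counts would otherwise
#'   mask for a planted fold exactly at the threshold).
#' @param gene_base_mean expected baseline count per transcript.
#' @param gene_depth nominal mapped fragments per library used as the
#'   normalization total: the planted transcripts are a tiny subset of a
#'   full transcriptome, so totals are dominated by unmodeled genes and do
#'   not move when one planted gene changes.
#' @param n_decoy_genes transcripts carrying no target site.
#' @param count_noise `"poisson"` or `"none"` for the transcript count model.
#' @param rng_seed integer seed; a fixed seed makes every output
#'   byte-identical across runs.
#' @return a `synth_config` list.
#' @export
synth_config <- function(genome_length = 60000,
                         n_mirna_loci = 10,
                         n_structural_loci = 4,
                         mature_length = 21,
                         loop_length = 15,
                         star_mismatches = 2,
                         libraries = default_library_design(),
                         base_depth = 50000,
                         effect_table = NULL,
                         adapter = "AGATCGGAAGAGCACACGT",
                         read_length = 50,
                         mature_weight = 5,
                         star_fraction = 0.1,
                         n_background_tags = 30,
                         background_weight = 30,
                         n_struct_frags = 10,
                         struct_weight = 100,
                         low_quality_fraction = 0,
                         target_scores = c(0, 0.5, 1, 2, 3),
                         target_fold = 2.5,
                         gene_base_mean = 500,
                         gene_depth = 1e6,
                         n_decoy_genes = 10,
                         count_noise = "poisson",
                         rng_seed = 1) {
  star_mismatches <- rep_len(star_mismatches, max(n_mirna_loci, 1))
  effect_table <- effect_table %||%
    tibble(locus = character(), genotype = character(), tissue = character(),
           treatment = character(), fold = numeric())
  stopifnot(all(effect_table$fold > 0))
  precursor_span <- 2 * mature_length + loop_length + 2
  if (genome_length < 2 * (precursor_span + 500)) {
    stop("genome_length must be at least 2 x (precursor span + 500) = ",
         2 * (precursor_span + 500))
  }
  cfg <- list(
    genome_length = genome_length, n_mirna_loci = n_mirna_loci,
    n_structural_loci = n_structural_loci, mature_length = mature_length,
    loop_length = loop_length, star_mismatches = star_mismatches,
    libraries = libraries, base_depth = base_depth,
    effect_table = effect_table, adapter = toupper(adapter),
    read_length = read_length, mature_weight = mature_weight,
    star_fraction = star_fraction, n_background_tags = n_background_tags,
    background_weight = background_weight, n_struct_frags = n_struct_frags,
    struct_weight = struct_weight,
    low_quality_fraction = low_quality_fraction,
    target_scores = target_scores, target_fold = target_fold,
    gene_base_mean = gene_base_mean, gene_depth = gene_depth,
    n_decoy_genes = n_decoy_genes,
    count_noise = count_noise, rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "synth_config"
  cfg
}

#' Default 2x2x2x2 library design
#'
#' @return tibble `genotype`, `tissue`, `treatment`, `replicate`, `library`.
#' @export
default_library_design <- function() {
  d <- tidyr::expand_grid(
    genotype = c("Col0", "cbp20"), tissue = c("root", "shoot"),
    treatment = c("air", "ethylene"), replicate = 1:2
  )
  d$library <- paste(d$genotype, d$tissue, d$treatment, d$replicate, sep = "_")
  d
}

stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + stage) %% 2147483647)
}

## substitute a base so that it pairs with `partner` neither WC nor G:U
non_pairing_base <- function(partner) {
  switch(partner,
         A = c("A", "G", "C"),  # A pairs only U
         G = c("A", "G"),       # G pairs C and U
         U = c("C", "U"), T = c("C", "U"),  # U pairs A and G
         C = c("A", "C", "U"))  # C pairs only G
}

## a substitution that cannot pair its partner nor the partner's neighbors,
## so the planted lesion folds as a clean point internal loop instead of
## letting the fold shift register; falls back to partner-only exclusion
non_pairing_base_clean <- function(partner, neighbors) {
  cand <- non_pairing_base(partner)
  for (nb in neighbors) {
    cand <- setdiff(cand, setdiff(c("A", "C", "G", "U"),
                                  non_pairing_base(nb)))
  }
  if (length(cand) == 0) cand <- non_pairing_base(partner)
  cand
}

#' Build a synthetic genome with planted miRNA and structural-RNA loci
#'
#' The genome is uniform random background (25% each base). Each miRNA locus
#' is planted as mature arm + loop + reverse complement of the mature with
#' exactly the configured number of non-pairing substitutions (so the
#' constructed duplex has a known mismatch ratio). Structural loci (tRNA,
#' rRNA, snRNA, snoRNA) are random intervals with class labels. Loci are
#' non-overlapping with a safety margin; coordinates in the returned truth
#' are 0-based half-open with explicit strand.
#'
#' @param config a [synth_config()].
#' @return list with `genome` (named character vector, one chromosome
#'   `chr1`) and `truth` (list: `mirna_loci`, `structural_loci`,
#'   `target_sites` tibbles).
#' @export
build_genome <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(stage_seed(config$rng_seed, 1))
  L <- config$genome_length
  genome_chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)

  occupied <- tibble(start = integer(), end = integer())
  place <- function(width, label, margin = 60) {
    for (i in 1:2000) {
      s <- sample.int(L - width, 1)  # 1-based start
      ok <- !any(s - margin < occupied$end & s + width + margin > occupied$start)
      if (ok) {
        occupied <<- dplyr::bind_rows(occupied,
                                      tibble(start = s, end = s + width))
        return(s)
      }
    }
    stop("infeasible packing: cannot place locus ", label,
         " (width ", width, ") without overlap")
  }

  ml <- config$mature_length
  empty_mirna <- tibble(
    locus = character(), chrom = character(), strand = character(),
    precursor_start = integer(), precursor_end = integer(),
    mature_start = integer(), mature_end = integer(),
    star_start = integer(), star_end = integer(),
    mature = character(), star = character(), star_mismatches = integer())
  mirna_rows <- purrr::map_dfr(seq_len(config$n_mirna_loci), function(i) {
    mature <- random_dna(ml)
    star <- revcomp(mature)
    nmm <- config$star_mismatches[i]
    if (nmm > 0) {
      ## star position j (1-based in star, 5'->3') pairs mature position
      ## ml - j + 1. Lesions go to interior positions and must pair
      ## neither the partner nor its neighbors: real duplex mismatches are
      ## point internal loops, and a substitution able to pair a neighbor
      ## would let the fold shift register into asymmetric bulges.
      interior <- 4:(ml - 3)
      mm_pos <- sort(sample(interior, min(nmm, length(interior))))
      star_ch <- seq_chars(star)
      mat_rna <- dna_to_rna(seq_chars(mature))
      for (j in mm_pos) {
        p <- ml - j + 1
        nbs <- mat_rna[intersect(c(p - 1, p + 1), seq_len(ml))]
        cand <- non_pairing_base_clean(mat_rna[p], nbs)
        star_ch[j] <- rna_to_dna(cand[sample.int(length(cand), 1)])
      }
      star <- paste(star_ch, collapse = "")
    }
    loop <- random_dna(config$loop_length)
    precursor <- paste0(mature, loop, star)
    strand <- sample(c("+", "-"), 1)
    s1 <- place(nchar(precursor), paste0("mir", i))  # 1-based
    planted <- if (strand == "+") precursor else revcomp(precursor)
    genome_chars[s1:(s1 + nchar(precursor) - 1)] <<- seq_chars(planted)
    p0 <- s1 - 1L  # 0-based precursor start
    if (strand == "+") {
      mat0 <- p0; star0 <- p0 + ml + config$loop_length
    } else {
      ## on minus strand the mature (5' arm of the precursor) sits at the
      ## right end of the genome interval
      mat0 <- p0 + nchar(precursor) - ml
      star0 <- p0
    }
    tibble(
      locus = sprintf("mir%02d", i), chrom = "chr1", strand = strand,
      precursor_start = p0, precursor_end = p0 + nchar(precursor),
      mature_start = mat0, mature_end = mat0 + ml,
      star_start = star0, star_end = star0 + nchar(star),
      mature = mature, star = star, star_mismatches = nmm
    )
  })

  if (nrow(mirna_rows) == 0) mirna_rows <- empty_mirna
  struct_classes <- c("tRNA", "rRNA", "snRNA", "snoRNA")
  struct_widths <- c(tRNA = 75, rRNA = 120, snRNA = 100, snoRNA = 90)
  structural_rows <- purrr::map_dfr(
    seq_len(config$n_structural_loci), function(i) {
      cls <- struct_classes[(i - 1) %% length(struct_classes) + 1]
      w <- struct_widths[[cls]]
      s1 <- place(w, paste0(cls, i))
      tibble(locus = sprintf("%s%02d", cls, i), chrom = "chr1",
             start = s1 - 1L, end = s1 - 1L + w, class = cls, strand = "+")
    })
  if (nrow(structural_rows) == 0) {
    structural_rows <- tibble(locus = character(), chrom = character(),
                              start = integer(), end = integer(),
                              class = character(), strand = character())
  }

  target_sites <- if (config$n_mirna_loci > 0) {
    tibble(
      locus = mirna_rows$locus,
      transcript = paste0("T_", mirna_rows$locus),
      intended_score = rep_len(config$target_scores, config$n_mirna_loci)
    )
  } else {
    tibble(locus = character(), transcript = character(),
           intended_score = numeric())
  }

  genome <- setNames(paste(genome_chars, collapse = ""), "chr1")
  truth <- list(mirna_loci = mirna_rows, structural_loci = structural_rows,
                target_sites = target_sites)
  list(genome = genome, truth = truth)
}

#' Structural and miRNA annotations from a synthetic truth record
#'
#' @param truth truth list from [build_genome()].
#' @return annotation tibble `chrom`, `start` (0-based), `end` (half-open),
#'   `strand`, `class`, `id`.
#' @export
truth_annotations <- function(truth) {
  dplyr::bind_rows(
    tibble(chrom = truth$structural_loci$chrom,
           start = truth$structural_loci$start,
           end = truth$structural_loci$end,
           strand = truth$structural_loci$strand,
           class = truth$structural_loci$class,
           id = truth$structural_loci$locus),
    tibble(chrom = truth$mirna_loci$chrom,
           start = truth$mirna_loci$precursor_start,
           end = truth$mirna_loci$precursor_end,
           strand = truth$mirna_loci$strand,
           class = "miRNA_primary_transcript",
           id = truth$mirna_loci$locus)
  )
}

condition_fold <- function(effect_table, locus, genotype, tissue, treatment) {
  hit <- effect_table[effect_table$locus == locus &
                        effect_table$genotype == genotype &
                        effect_table$tissue == tissue &
                        effect_table$treatment == treatment, ]
  if (nrow(hit) == 0) 1 else hit$fold[1]
}

#' Simulate small-RNA libraries from planted truth
#'
#' Builds a tag universe (mature tags, star tags at a fraction of mature,
#' structural-RNA fragments including lengths outside 18-28 nt, random
#' genome-derived background tags), multiplies mature/star weights by the
#' per-condition fold effects, draws reads multinomially at the configured
#' depth, appends the 3' adapter and truncates to the read length.
#'
#' @param truth truth list from [build_genome()]; requires the genome to
#'   sample structural fragments and background tags, passed as `genome`.
#' @param config a [synth_config()].
#' @param genome the genome from [build_genome()].
#' @return named list of read tibbles (one per library). The expected
#'   per-library tag proportions are attached as `attr(, "true_weights")`
#'   (tibble `tag`, `origin`, `locus`, one weight column per library).
#' @export
simulate_small_rna_libraries <- function(truth, config, genome) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(stage_seed(config$rng_seed, 2))
  g <- genome[[1]]
  ml <- truth$mirna_loci

  tagdefs <- list()
  if (nrow(ml) > 0) {
    tagdefs$mature <- tibble(tag = rna_to_dna(ml$mature), origin = "mature",
                             locus = ml$locus, weight = config$mature_weight)
    tagdefs$star <- tibble(
      tag = rna_to_dna(ml$star), origin = "star", locus = ml$locus,
      weight = config$mature_weight * config$star_fraction)
  }
  sl <- truth$structural_loci
  if (nrow(sl) > 0 && config$n_struct_frags > 0) {
    tagdefs$struct <- purrr::map_dfr(seq_len(nrow(sl)), function(i) {
      lens <- sample(15:35, config$n_struct_frags, replace = TRUE)
      starts <- vapply(lens, function(w) {
        sl$start[i] + sample.int(sl$end[i] - sl$start[i] - w + 1, 1) - 1L
      }, integer(1))
      tibble(tag = substring(g, starts + 1, starts + lens),
             origin = "structural", locus = sl$locus[i],
             weight = config$struct_weight)
    })
  }
  if (config$n_background_tags > 0) {
    lens <- sample(18:28, config$n_background_tags, replace = TRUE)
    planted <- dplyr::bind_rows(
      tibble(start = ml$precursor_start, end = ml$precursor_end),
      tibble(start = sl$start, end = sl$end))
    starts <- vapply(lens, function(w) {
      for (k in 1:200) {
        s <- sample.int(nchar(g) - w, 1) - 1L
        if (!any(s < planted$end & s + w > planted$start)) return(s)
      }
      s
    }, integer(1))
    tagdefs$background <- tibble(
      tag = substring(g, starts + 1, starts + lens), origin = "background",
      locus = NA_character_, weight = config$background_weight)
  }
  tags <- dplyr::bind_rows(tagdefs)
  tags <- tags[!duplicated(tags$tag), , drop = FALSE]

  libs <- config$libraries
  reads <- vector("list", nrow(libs))
  names(reads) <- libs$library
  weights_out <- tags[, c("tag", "origin", "locus")]
  for (li in seq_len(nrow(libs))) {
    w <- tags$weight
    for (k in seq_len(nrow(tags))) {
      if (tags$origin[k] %in% c("mature", "star")) {
        w[k] <- w[k] * condition_fold(config$effect_table, tags$locus[k],
                                      libs$genotype[li], libs$tissue[li],
                                      libs$treatment[li])
      }
    }
    weights_out[[libs$library[li]]] <- w / sum(w)
    depth <- config$base_depth
    if (depth == 0) {
      reads[[li]] <- tibble(id = character(), sequence = character(),
                            quality = character())
      next
    }
    draws <- as.vector(stats::rmultinom(1, depth, w))
    seqs <- rep(tags$tag, draws)
    seqs <- seqs[sample.int(length(seqs))]
    raw <- substr(paste0(seqs, strrep(config$adapter, 4)), 1,
                  config$read_length)
    qual <- strrep("I", nchar(raw))
    if (config$low_quality_fraction > 0) {
      low <- runif(length(raw)) < config$low_quality_fraction
      qual[low] <- strrep("#", nchar(raw[low]))
    }
    reads[[li]] <- tibble(
      id = sprintf("%s_read%06d", libs$library[li], seq_along(raw)),
      sequence = raw, quality = qual)
  }
  attr(reads, "true_weights") <- weights_out
  reads
}

#' Simulate a transcriptome with planted target sites and counts
#'
#' Each planted miRNA locus gets a host transcript embedding a target site
#' constructed to score exactly the intended penalty (see [design_site()]);
#' decoy transcripts carry no site. Counts realize the planted differential
#' effects: a transcript hosting the target of an up-regulated miRNA is
#' down-regulated by `target_fold` in exactly the conditions where its
#' miRNA goes up. Noise is Poisson around the expectation, or off.
#'
#' @param truth truth list from [build_genome()].
#' @param config a [synth_config()].
#' @return list with `transcripts` (named character vector), `counts`
#'   (tibble `feature` x library), `lengths` (named), `totals` (nominal
#'   per-library mapped totals, see `gene_depth`), `site_table` (tibble
#'   `transcript`, `locus`, `site_start` 0-based, `site_end` half-open,
#'   `intended_score`), and `true_differential` (tibble `feature`,
#'   `genotype`, `tissue`, `direction`, `fold` for the ethylene-vs-air
#'   contrast).
#' @export
simulate_transcriptome_counts <- function(truth, config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(stage_seed(config$rng_seed, 3))
  ml <- truth$mirna_loci
  ts <- truth$target_sites

  transcripts <- character(0); lengths <- integer(0)
  site_rows <- list()
  for (i in seq_len(nrow(ts))) {
    mature <- dna_to_rna(ml$mature[match(ts$locus[i], ml$locus)])
    site <- design_site(mature, ts$intended_score[i])
    up <- random_dna(180); down <- random_dna(180)
    seqc <- paste0(up, rna_to_dna(site), down)
    transcripts[ts$transcript[i]] <- seqc
    lengths[ts$transcript[i]] <- nchar(seqc)
    site_rows[[i]] <- tibble(
      transcript = ts$transcript[i], locus = ts$locus[i],
      site_start = nchar(up), site_end = nchar(up) + nchar(site),
      intended_score = ts$intended_score[i])
  }
  for (i in seq_len(config$n_decoy_genes)) {
    id <- sprintf("DECOY%02d", i)
    transcripts[id] <- random_dna(sample(300:1500, 1))
    lengths[id] <- nchar(transcripts[id])
  }
  site_table <- dplyr::bind_rows(site_rows)
  if (nrow(site_table) == 0) {
    site_table <- tibble(transcript = character(), locus = character(),
                         site_start = integer(), site_end = integer(),
                         intended_score = numeric())
  }

  libs <- config$libraries
  counts <- tibble(feature = names(transcripts))
  diff_rows <- list()
  ## conditions where a locus is up-regulated by ethylene
  eff <- config$effect_table
  for (li in seq_len(nrow(libs))) {
    mu <- rep(config$gene_base_mean, length(transcripts))
    names(mu) <- names(transcripts)
    for (k in seq_len(nrow(site_table))) {
      f <- condition_fold(eff, site_table$locus[k], libs$genotype[li],
                          libs$tissue[li], libs$treatment[li])
      if (f > 1) {
        mu[site_table$transcript[k]] <-
          mu[site_table$transcript[k]] / config$target_fold
      }
    }
    counts[[libs$library[li]]] <- unname(if (config$count_noise == "poisson") {
      rpois(length(mu), mu)
    } else {
      round(mu)
    })
  }
  for (k in seq_len(nrow(site_table))) {
    up_conds <- eff[eff$locus == site_table$locus[k] & eff$fold > 1 &
                      eff$treatment == "ethylene", ]
    if (nrow(up_conds) > 0) {
      diff_rows[[length(diff_rows) + 1]] <- tibble(
        feature = site_table$transcript[k], genotype = up_conds$genotype,
        tissue = up_conds$tissue, direction = "down",
        fold = config$target_fold)
    }
  }
  true_differential <- dplyr::bind_rows(diff_rows)
  if (length(diff_rows) == 0) {
    true_differential <- tibble(feature = character(), genotype = character(),
                                tissue = character(), direction = character(),
                                fold = numeric())
  }
  list(transcripts = transcripts, counts = counts, lengths = lengths,
       totals = setNames(rep(config$gene_depth, nrow(libs)), libs$library),
       site_table = site_table, true_differential = true_differential)
}

#' Construct a target site with an intended penalty score
#'
#' Starts from the exact reverse complement of the mature miRNA and
#' introduces G:U wobbles and mismatches whose position-weighted penalties
#' sum exactly to `score` under the scoring rules (+1 mismatch/bulge/gap,
#' +0.5 G:U, doubled at miRNA positions 2-13). Positions 10 and 11 are left
#' paired so the canonical cleavage site stays defined. The site is returned
#' 5'->3' as RNA.
#'
#' @param mirna mature miRNA sequence, 5'->3' (RNA or DNA).
#' @param score intended penalty score (multiple of 0.5).
#' @return site sequence (RNA, 5'->3').
#' @export
design_site <- function(mirna, score) {
  mirna <- dna_to_rna(toupper(mirna))
  n <- nchar(mirna)
  m <- seq_chars(mirna)
  ## site position j (1-based, 5'->3') pairs miRNA position n - j + 1
  site <- seq_chars(dna_to_rna(revcomp(rna_to_dna(mirna))))
  remaining <- score
  ## candidate miRNA positions, fine (undoubled, 14..n) first
  undoubled <- setdiff(c(1, 14:n), c(10, 11))
  doubled <- setdiff(2:13, c(10, 11))
  used <- integer(0)
  lesion_at <- function(pos, type) {
    j <- n - pos + 1
    if (type == "gu") {
      ## G:U wobble: miRNA G across from site U, or miRNA U across from G
      site[j] <<- if (m[pos] == "G") "U" else "G"
    } else {
      site[j] <<- sample(non_pairing_base(m[pos]), 1)
    }
    used <<- c(used, pos)
  }
  take <- function(pool, need_gu = FALSE) {
    for (p in rev(setdiff(pool, used))) {
      if (!need_gu || m[p] %in% c("G", "U")) return(p)
    }
    NA_integer_
  }
  while (remaining > 0) {
    if (remaining >= 2 && !is.na(p <- take(doubled))) {
      lesion_at(p, "mismatch"); remaining <- remaining - 2
    } else if (remaining >= 1 && !is.na(p <- take(undoubled))) {
      lesion_at(p, "mismatch"); remaining <- remaining - 1
    } else if (remaining >= 1 && !is.na(p <- take(doubled, need_gu = TRUE))) {
      lesion_at(p, "gu"); remaining <- remaining - 1
    } else if (remaining == 0.5 && !is.na(p <- take(undoubled,
                                                    need_gu = TRUE))) {
      lesion_at(p, "gu"); remaining <- remaining - 0.5
    } else {
      stop("intended score ", score, " unreachable for this miRNA sequence")
    }
  }
  paste(site, collapse = "")
}
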