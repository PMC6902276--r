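# Seeded synthetic-data generator: genomes with intact gene models, planted
# variant sets with ground truth, and engineered ambiguous-INDEL loci where
# a deletion has several equal-cost placements under uniform scoring, only
# one of which preserves the splice motif.

#' Specification for a synthetic fixture genome
#'
#' @param seed Integer seed; all fixture operations are deterministic under
#'   it (the global RNG state is restored afterwards).
#' @param n_chromosomes,chromosome_length,n_genes Genome layout. `n_genes`
#'   is per chromosome.
#' @param exons_per_gene,intron_length,cds_exon_length Integer ranges
#'   `c(min, max)` sampled per gene/exon/intron.
#' @param n_snp,n_ins,n_del Planted variant counts (genome-wide) for
#'   [plant_variants()].
#' @param indel_max Maximum planted INDEL length in bp.
#' @param n_ambiguous_loci Number of transcripts to receive an engineered
#'   ambiguous-INDEL locus.
#' @param minus_strand_frac Fraction of genes placed on the minus strand.
#' @return Object of class `zl_fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_chromosomes = 1L, chromosome_length = 10000L,
                         n_genes = 5L, exons_per_gene = c(1L, 3L),
                         intron_length = c(40L, 120L), cds_exon_length = c(30L, 150L),
                         n_snp = 0L, n_ins = 0L, n_del = 0L, indel_max = 10L,
                         n_ambiguous_loci = 0L, minus_strand_frac = 0.5) {
  spec <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
               chromosome_length = as.integer(chromosome_length),
               n_genes = as.integer(n_genes),
               exons_per_gene = as.integer(exons_per_gene),
               intron_length = as.integer(intron_length),
               cds_exon_length = as.integer(cds_exon_length),
               n_snp = as.integer(n_snp), n_ins = as.integer(n_ins),
               n_del = as.integer(n_del), indel_max = as.integer(indel_max),
               n_ambiguous_loci = as.integer(n_ambiguous_loci),
               minus_strand_frac = minus_strand_frac)
  counts <- c(spec$n_snp, spec$n_ins, spec$n_del, spec$n_ambiguous_loci)
  if (any(counts < 0L)) stop_contract("fixture counts must be >= 0")
  if (spec$intron_length[1] < 6L) stop_contract("introns must respect the ORF minimum intron length")
  if (spec$cds_exon_length[1] < 10L) stop_contract("CDS exons must respect the ORF minimum CDS length")
  structure(spec, class = "zl_fixture_spec")
}

.codons <- {
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  list(coding = setdiff(all3, c("TAA", "TAG", "TGA")), stop = c("TAA", "TAG", "TGA"))
}

# One gene in transcript orientation: CDS pieces interleaved with GT..AG
# introns; returns sequence and transcript-local CDS intervals.
.make_gene <- function(spec) {
  n_ex <- sample(spec$exons_per_gene[1]:spec$exons_per_gene[2], 1L)
  ex_len <- sample(spec$cds_exon_length[1]:spec$cds_exon_length[2], n_ex, replace = TRUE)
  total <- sum(ex_len)
  ex_len[n_ex] <- ex_len[n_ex] - total %% 3L  # total CDS length divisible by 3
  n_codon <- sum(ex_len) %/% 3L
  cds <- paste0("ATG",
                paste(sample(.codons$coding, n_codon - 2L, replace = TRUE), collapse = ""),
                sample(.codons$stop, 1L))
  introns <- if (n_ex > 1L) {
    vapply(seq_len(n_ex - 1L), function(k) {
      len <- sample(spec$intron_length[1]:spec$intron_length[2], 1L)
      paste0("GT", random_dna(len - 4L), "AG")
    }, character(1))
  } else character(0)
  pieces <- character(2L * n_ex - 1L)
  off <- c(0L, cumsum(ex_len))
  pieces[seq(1L, length(pieces), by = 2L)] <-
    substring(cds, off[-length(off)] + 1L, off[-1L])
  if (n_ex > 1L) pieces[seq(2L, length(pieces), by = 2L)] <- introns
  lens <- nchar(pieces)
  starts <- c(0L, cumsum(lens))[seq_along(lens)]
  exon_idx <- seq(1L, length(pieces), by = 2L)
  list(seq = paste(pieces, collapse = ""),
       cds_local = cbind(start = starts[exon_idx], end = starts[exon_idx] + lens[exon_idx]))
}

#' Generate a genome with an intact annotation
#'
#' Genes are placed sequentially with random intergenic spacers (GC ~ 0.5);
#' every generated transcript is verified ORF-intact under default
#' [orf_params()] before returning. Deterministic under `spec$seed`.
#'
#' @param spec [fixture_spec()].
#' @return List with `genome` (named character vector) and `annotation`
#'   (annotation tibble).
#' @export
generate_genome_with_annotation <- function(spec) {
  stopifnot(inherits(spec, "zl_fixture_spec"))
  with_seed(spec$seed, {
    genome <- character(0)
    tx_rows <- list()
    for (ci in seq_len(spec$n_chromosomes)) {
      chrom <- paste0("chr", ci)
      genes <- lapply(seq_len(spec$n_genes), function(g) .make_gene(spec))
      glen <- vapply(genes, function(g) nchar(g$seq), integer(1))
      spacer_min <- 120L
      if (sum(glen) + (spec$n_genes + 1L) * spacer_min > spec$chromosome_length) {
        stop_contract("genes do not fit on the chromosome; increase chromosome_length")
      }
      free <- spec$chromosome_length - sum(glen)
      cuts <- sort(sample.int(free - (spec$n_genes + 1L) * spacer_min + spec$n_genes,
                              spec$n_genes))
      gaps <- diff(c(0L, cuts, free - (spec$n_genes + 1L) * spacer_min + spec$n_genes + 1L)) - 1L
      gaps <- gaps + spacer_min
      pieces <- character(2L * spec$n_genes + 1L)
      offset <- 0L
      for (g in seq_len(spec$n_genes)) {
        pieces[2L * g - 1L] <- random_dna(gaps[g])
        offset <- offset + gaps[g]
        strand <- if (stats::runif(1) < spec$minus_strand_frac) "-" else "+"
        gseq <- genes[[g]]$seq
        cdl <- genes[[g]]$cds_local
        L <- nchar(gseq)
        if (strand == "-") {
          pieces[2L * g] <- revcomp(gseq)
          cds <- cbind(start = offset + L - cdl[, 2], end = offset + L - cdl[, 1])
          cds <- cds[rev(seq_len(nrow(cds))), , drop = FALSE]
        } else {
          pieces[2L * g] <- gseq
          cds <- cbind(start = offset + cdl[, 1], end = offset + cdl[, 2])
        }
        gid <- paste0("g", ci, "_", g)
        tx_rows[[length(tx_rows) + 1L]] <- tibble(
          transcript_id = paste0(gid, ".1"), gene_id = gid, chrom = chrom,
          strand = strand, exons = list(cds), cds = list(cds)
        )
        offset <- offset + L
      }
      pieces[2L * spec$n_genes + 1L] <- random_dna(spec$chromosome_length - offset)
      genome[[chrom]] <- paste(pieces, collapse = "")
    }
    txs <- bind_rows(tx_rows)
    ann <- transcripts_to_annotation(txs)
    bad <- filter(orf_check_annotation(ann, genome), !.data$intact)
    if (nrow(bad)) {
      stop_contract(paste0("generator produced a broken ORF: ", bad$transcript_id[[1]]))
    }
    list(genome = genome, annotation = ann)
  })
}

#' Plant variants into a genome with ground truth
#'
#' Plants the SNP/INS/DEL counts requested by the spec at non-overlapping,
#' non-adjacent positions and returns the mutated genome together with the
#' truth set in reference coordinates (VCF-anchored records).
#'
#' @param genome Named character vector.
#' @param annotation Annotation tibble (unused for placement, carried for
#'   callers that want gene-aware follow-ups).
#' @param spec [fixture_spec()] (uses the variant counts and seed).
#' @return List with `genome` (mutated) and `truth` (variant tibble).
#' @export
plant_variants <- function(genome, annotation, spec) {
  stopifnot(inherits(spec, "zl_fixture_spec"))
  with_seed(spec$seed + 104729L, {
    kinds <- c(rep("SNP", spec$n_snp), rep("INS", spec$n_ins), rep("DEL", spec$n_del))
    if (!length(kinds)) return(list(genome = genome, truth = variant_tibble(
      tibble(chrom = character(0), pos = integer(0), ref = character(0), alt = character(0))
    )))
    kinds <- sample(kinds)
    lens <- nchar(genome)
    occupied <- lapply(names(genome), function(ch) cbind(start = integer(0), end = integer(0)))
    names(occupied) <- names(genome)
    rows <- vector("list", length(kinds))
    for (k in seq_along(kinds)) {
      placed <- FALSE
      for (try in 1:200) {
        ch <- sample(names(genome), 1L, prob = lens / sum(lens))
        need <- if (kinds[k] == "DEL") spec$indel_max + 2L else 2L
        p <- sample.int(lens[[ch]] - need - 2L, 1L)
        span <- c(p - 2L, p + need + 2L)  # keep >= 2 bp between variants
        occ <- occupied[[ch]]
        if (any(occ[, 1] < span[2] & occ[, 2] > span[1])) next
        anchor <- substr0(genome[[ch]], p, p + 1L)
        if (kinds[k] == "SNP") {
          alt <- sample(setdiff(c("A", "C", "G", "T"), anchor), 1L)
          rows[[k]] <- tibble(chrom = ch, pos = p, ref = anchor, alt = alt)
        } else if (kinds[k] == "INS") {
          ins <- random_dna(sample.int(spec$indel_max, 1L))
          rows[[k]] <- tibble(chrom = ch, pos = p, ref = anchor, alt = paste0(anchor, ins))
        } else {
          d <- sample.int(spec$indel_max, 1L)
          ref <- substr0(genome[[ch]], p, p + d + 1L)
          rows[[k]] <- tibble(chrom = ch, pos = p, ref = ref, alt = anchor)
        }
        occupied[[ch]] <- rbind(occ, span)
        placed <- TRUE
        break
      }
      if (!placed) stop_contract("variant density too high to avoid overlaps")
    }
    truth <- variant_tibble(bind_rows(rows))
    list(genome = apply_variants(genome, truth)$genome, truth = truth)
  })
}

# 13-mer with period-defining content: no T anywhere and a leading C, so no
# stop codon can arise from it in any reading frame even across the
# exon-junction codon; terminal AG serves as the splice acceptor.
.ambig_repeat <- "CAGCAGCAGCAAG"

#' Engineer an ambiguous-INDEL locus in an intron
#'
#' Rewrites the 3' end of a CDS-internal intron and the start of the
#' downstream exon so the 39 bp across the acceptor junction are three
#' copies of a 13-mer ending in `AG`. A 13-bp deletion in that region then
#' has several equal-cost placements under uniform scoring — one wholly
#' inside the intron (splice motif preserved) and one spanning the acceptor
#' splice site — while zebraic scoring penalizes the splice-site columns and
#' keeps the gap intronic. The reference genome is modified in place
#' (ORF-intactness of the transcript is preserved by construction) and the
#' descriptor records both deletion placements as variant records producing
#' byte-identical pseudo-genomes.
#'
#' @param genome Named character vector (reference).
#' @param tx One-row transcript tibble; must be plus-strand with a
#'   CDS-internal intron of length >= 32 and a downstream exon of length
#'   >= 16.
#' @return List with `genome` (modified reference) and `locus`, a one-row
#'   tibble with the intronic and splice-crossing deletion records.
#' @export
plant_ambiguous_indel_locus <- function(genome, tx) {
  if (tx$strand != "+") stop_contract("ambiguous locus requires a plus-strand transcript")
  introns <- cds_introns(tx)
  cd <- tx$cds[[1]]
  ok <- which(introns[, 2] - introns[, 1] >= 32L)
  ok <- ok[vapply(ok, function(k) {
    ex_next <- cd[k + 1L, ]
    ex_next[2] - ex_next[1] >= 16L
  }, logical(1))]
  if (!length(ok)) stop_contract("no intron long enough for an ambiguous locus")
  k <- ok[[1]]
  e <- introns[k, 2]  # exclusive intron end == downstream exon start
  ch <- tx$chrom
  s <- genome[[ch]]
  Tm <- .ambig_repeat
  region <- paste0(Tm, Tm, Tm)
  genome[[ch]] <- paste0(substr0(s, 0L, e - 26L), region, substr0(s, e + 13L, nchar(s)))
  seqnow <- genome[[ch]]
  rec <- function(p, len) {  # anchored deletion of [p, p+len)
    tibble(chrom = ch, pos = p - 1L,
           ref = substr0(seqnow, p - 1L, p + len),
           alt = substr0(seqnow, p - 1L, p))
  }
  if (!check_orf_state(tx, genome)$intact) {
    stop_contract("ambiguous-locus rewrite broke the transcript ORF")
  }
  intronic <- rec(e - 26L, 13L)   # first copy: wholly intronic
  crossing <- rec(e - 2L, 13L)    # straddles the junction: removes the
                                  # acceptor AG and the first 11 exon bases
  locus <- tibble(
    chrom = ch, transcript_id = tx$transcript_id,
    intron_start = introns[k, 1], intron_end = e,
    region_start = e - 26L, region_end = e + 13L, del_len = 13L,
    pos_intronic = intronic$pos, ref_intronic = intronic$ref, alt_intronic = intronic$alt,
    pos_crossing = crossing$pos, ref_crossing = crossing$ref, alt_crossing = crossing$alt
  )
  list(genome = genome, locus = locus)
}

#' Relocate a genomic segment (structural-variation fixture)
#'
#' Moves `[seg_start, seg_end)` of one chromosome to position `dest`
#' (coordinates in the original sequence, outside the segment), adjusting
#' annotation coordinates. Features straddling a cut point are a contract
#' error.
#'
#' @param genome Named character vector.
#' @param annotation Annotation tibble.
#' @param chrom Chromosome name.
#' @param seg_start,seg_end,dest 0-based coordinates.
#' @return List with `genome` and `annotation`.
#' @export
relocate_segment <- function(genome, annotation, chrom, seg_start, seg_end, dest) {
  seg_start <- as.integer(seg_start); seg_end <- as.integer(seg_end)
  dest <- as.integer(dest)
  s <- genome[[chrom]]
  L <- nchar(s)
  if (dest > seg_start && dest < seg_end) stop_contract("destination inside the segment")
  A <- c(0L, seg_start); B <- c(seg_start, seg_end); C <- c(seg_end, L)
  pieces <- if (dest >= seg_end) {
    list(A, c(seg_end, dest), B, c(dest, L))
  } else {
    list(c(0L, dest), B, c(dest, seg_start), C)
  }
  pieces <- Filter(function(p) p[2] > p[1], pieces)
  new_seq <- paste(vapply(pieces, function(p) substr0(s, p[1], p[2]), character(1)),
                   collapse = "")
  offsets <- c(0L, cumsum(vapply(pieces, function(p) p[2] - p[1], integer(1))))
  map_pos <- function(p, is_end = FALSE) {
    pp <- if (is_end) p - 1L else p
    for (k in seq_along(pieces)) {
      if (pp >= pieces[[k]][1] && pp < pieces[[k]][2]) {
        return(offsets[k] + (pp - pieces[[k]][1]) + if (is_end) 1L else 0L)
      }
    }
    stop_contract("position outside chromosome")
  }
  ann <- validate_annotation(annotation)
  idx <- which(ann$chrom == chrom)
  for (i in idx) {
    ns <- map_pos(ann$start[i]); ne <- map_pos(ann$end[i], is_end = TRUE)
    if (ne - ns != ann$end[i] - ann$start[i]) {
      stop_contract(paste0("feature straddles a relocation cut point: ",
                           ann$type[i], " at ", ann$start[i]))
    }
    ann$start[i] <- ns; ann$end[i] <- ne
  }
  genome[[chrom]] <- new_seq
  list(genome = genome, annotation = arrange(ann, .data$chrom, .data$start, .data$end))
}
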