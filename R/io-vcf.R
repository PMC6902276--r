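#' Read and write variant records (VCF)
#'
#' Variants are represented internally as a tibble with columns `chrom`,
#' `pos` (0-based position of the leftmost affected base), `ref`, `alt`
#' (non-empty upper-case allele strings; INDELs keep the VCF left anchor
#' base), and derived `kind` in `SNP`, `INS`, `DEL`, `MNP`. Multi-allelic
#' records are split into one row per ALT allele on read.
#'
#' @param path VCF file path.
#' @param genome Optional named character vector of reference sequences; when
#'   supplied every REF allele is checked against it and a mismatch is a
#'   validation error.
#' @return `read_vcf()`: variant tibble.
#' @export
read_vcf <- function(path, genome = NULL) {
  check_file(path)
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop_format(paste0("malformed VCF in ", path, ": ", conditionMessage(e)))
  )
  fix <- vcfR::getFIX(v)
  if (is.null(fix) || nrow(fix) == 0L) stop_format(paste0("no variant records in ", path))
  out <- tibble(
    chrom = as.character(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]) - 1L,
    ref = toupper(as.character(fix[, "REF"])),
    alt = toupper(as.character(fix[, "ALT"]))
  )
  out <- tidyr::separate_rows(out, "alt", sep = ",")
  out <- filter(out, !.data$alt %in% c(".", "*", ""))
  if (!all(nzchar(out$ref))) stop_format("VCF record with empty REF allele")
  out <- variant_tibble(out)
  # REF agreement only: split multi-allelic rows legitimately share a span
  if (!is.null(genome)) validate_variants(genome, out, check_overlap = FALSE)
  out
}

#' Collapse multi-allelic sites to their first ALT allele
#'
#' Pseudo-genome construction is haploid: when several ALT alleles share a
#' site, the first is kept (genotype-aware selection is out of scope).
#'
#' @param variants Variant tibble.
#' @return Variant tibble with one record per site.
#' @export
collapse_multiallelic <- function(variants) {
  v <- variant_tibble(variants)
  distinct(v, .data$chrom, .data$pos, .keep_all = TRUE)
}

#' @rdname read_vcf
#' @param variants Variant tibble.
#' @return `write_vcf()`: `path`, invisibly. Records are written as minimal
#'   8-column VCF 4.2 (no genotype columns).
#' @export
write_vcf <- function(variants, path, genome = NULL) {
  variants <- variant_tibble(variants)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=zebralift",
    if (!is.null(genome)) {
      paste0("##contig=<ID=", names(genome), ",length=", nchar(genome), ">")
    },
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", sep = "\t")
  )
  body <- if (nrow(variants)) {
    v <- arrange(variants, .data$chrom, .data$pos)
    paste(v$chrom, v$pos + 1L, ".", v$ref, v$alt, ".", ".", ".", sep = "\t")
  } else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Construct / normalize a variant tibble
#'
#' @param x Data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @return Variant tibble sorted by position with a derived `kind` column.
#' @export
variant_tibble <- function(x) {
  need <- c("chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    stop_contract(paste0("variants missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  v <- as_tibble(x)[need]
  v$pos <- as.integer(v$pos)
  v$ref <- toupper(v$ref)
  v$alt <- toupper(v$alt)
  if (nrow(v)) {
    if (any(!nzchar(v$ref)) || any(!nzchar(v$alt))) {
      stop_validation("variant alleles must be non-empty")
    }
    chars <- unique(seq_chars(paste(c(v$ref, v$alt), collapse = "")))
    if (!all(is_iupac(chars))) {
      stop_validation("variant alleles contain non-IUPAC characters")
    }
  }
  rl <- nchar(v$ref); al <- nchar(v$alt)
  v$kind <- dplyr::case_when(
    rl == al & rl == 1L & v$ref != v$alt ~ "SNP",
    rl == al ~ "MNP",
    al > rl ~ "INS",
    TRUE ~ "DEL"
  )
  arrange(v, .data$chrom, .data$pos)
}

#' Validate variants against a reference genome
#'
#' Checks chromosome presence, bounds, REF allele agreement with the genome
#' sequence, and that no two records overlap in reference span.
#'
#' @param genome Named character vector of sequences.
#' @param variants Variant tibble.
#' @param check_overlap Require non-overlapping reference spans (default).
#' @return `variants`, invisibly.
#' @export
validate_variants <- function(genome, variants, check_overlap = TRUE) {
  v <- variant_tibble(variants)
  bad_chrom <- setdiff(unique(v$chrom), names(genome))
  if (length(bad_chrom)) {
    stop_validation(paste0("variant chromosome not in genome: ", bad_chrom[[1]]))
  }
  for (ch in unique(v$chrom)) {
    vv <- filter(v, .data$chrom == ch)
    L <- nchar(genome[[ch]])
    ends <- vv$pos + nchar(vv$ref)
    if (any(vv$pos < 0L) || any(ends > L)) {
      stop_validation(paste0("variant out of bounds on ", ch))
    }
    obs <- substring(genome[[ch]], vv$pos + 1L, ends)
    bad <- which(obs != vv$ref)
    if (length(bad)) {
      stop_validation(paste0(
        "REF allele mismatch at ", ch, ":", vv$pos[bad[[1]]] + 1L,
        " (VCF REF '", vv$ref[bad[[1]]], "', genome '", obs[bad[[1]]], "')"
      ))
    }
    if (check_overlap && nrow(vv) > 1L) {
      ov <- which(vv$pos[-1L] < ends[-length(ends)])
      if (length(ov)) {
        i <- ov[[1]]
        stop_validation(paste0(
          "overlapping variants on ", ch, ": ",
          vv$pos[i] + 1L, " ", vv$ref[i], ">", vv$alt[i], " and ",
          vv$pos[i + 1L] + 1L, " ", vv$ref[i + 1L], ">", vv$alt[i + 1L]
        ))
      }
    }
  }
  invisible(v)
}
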