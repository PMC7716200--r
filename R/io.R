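# Plain-text I/O: a narrow biallelic-SNP VCF reader/writer (GT/GP/DS),
# pileup TSV, and headered CSV artifacts.

#' Write a haplotype panel as a phased VCF
#'
#' Consecutive haplotype pairs become diploid samples with phased GT
#' ("0|1").  Sample ids carry the population label of the pair's first
#' haplotype.
#'
#' @param panel a [haplotype_panel()].
#' @param path output file (plain text, VCF 4.2).
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  H <- nrow(panel$alleles)
  stopifnot(H %% 2L == 0L)
  ns <- H / 2L
  samp <- sprintf("%s_s%03d", panel$pop_label[2 * seq_len(ns) - 1L],
                  seq_len(ns))
  gt <- vapply(seq_len(ns), function(i)
    paste0(panel$alleles[2L * i - 1L, ], "|", panel$alleles[2L * i, ]),
    character(ncol(panel$alleles)))
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samp), collapse = "\t"))
  vt <- panel$variant_table
  body <- data.table::data.table(
    vt$chrom, vt$pos, sprintf("%s_%d", vt$chrom, vt$pos), vt$ref, vt$alt,
    ".", "PASS", ".", "GT")
  body <- cbind(body, data.table::as.data.table(gt))
  writeLines(hdr, path)
  data.table::fwrite(body, path, sep = "\t", append = TRUE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write imputed posteriors for one sample as a VCF
#'
#' FORMAT carries GT (hard call, unphased), GP (RR,RA,AA probabilities to 4
#' decimals, round-half-to-even) and DS (dosage); the per-site FT field
#' notes PASS or LOWGP from the GP_max rule.
#'
#' @param posteriors a `site_posterior` data.frame from [impute_sample()].
#' @param variant_table data.frame with chrom, pos, ref, alt for the sites.
#' @param sample sample id.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_imputed_vcf <- function(posteriors, variant_table, sample, path) {
  stopifnot(nrow(posteriors) == nrow(variant_table))
  gt <- c("0/0", "0/1", "1/1")[posteriors$hard_call + 1L]
  fmt4 <- function(x) formatC(round(x, 4L), format = "f", digits = 4L)
  gp <- paste(fmt4(posteriors$gp_rr), fmt4(posteriors$gp_ra),
              fmt4(posteriors$gp_aa), sep = ",")
  rec <- paste(gt, gp, fmt4(posteriors$dosage),
               ifelse(posteriors$pass, "PASS", "LOWGP"), sep = ":")
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=GP,Number=3,Type=Float,Description=\"Genotype probabilities RR,RA,AA\">",
           "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alt-allele dosage\">",
           "##FORMAT=<ID=FT,Number=1,Type=String,Description=\"Per-call filter (GP_max rule)\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample), collapse = "\t"))
  body <- data.table::data.table(
    variant_table$chrom, variant_table$pos,
    sprintf("%s_%d", variant_table$chrom, variant_table$pos),
    variant_table$ref, variant_table$alt, ".", "PASS", ".",
    "GT:GP:DS:FT", rec)
  writeLines(hdr, path)
  data.table::fwrite(body, path, sep = "\t", append = TRUE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a biallelic-SNP VCF (GT, and GP/DS when present)
#'
#' Parses VCF 4.2 text.  Indel and multi-allelic records are skipped with a
#' logged count; malformed records raise an error with the file line
#' number.  GT is parsed phased or unphased; when every record of every
#' sample is phased, per-sample haplotypes are also returned.
#'
#' @param path VCF file (plain text).
#' @return list: `variant_table` (chrom, pos, ref, alt), `genotypes`
#'   (samples x variants 0/1/2, NA for missing), `gp` (list of samples x
#'   variants matrices gp_rr/gp_ra/gp_aa, or NULL), `dosage` (matrix or
#'   NULL), `haplotypes` (2 per sample, or NULL), `samples`, `n_skipped`.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  hdr_idx <- grep("^#CHROM", lines)
  if (length(hdr_idx) != 1L) stop("not a VCF: missing #CHROM header line")
  cols <- strsplit(lines[hdr_idx], "\t", fixed = TRUE)[[1]]
  if (length(cols) < 10L) stop("VCF has no sample columns")
  samples <- cols[-(1:9)]
  body_idx <- seq.int(hdr_idx + 1L, length(lines))
  body_idx <- body_idx[nzchar(lines[body_idx])]
  nS <- length(samples)
  keep_rows <- list(); n_skipped <- 0L
  bases <- c("A", "C", "G", "T")
  for (li in body_idx) {
    f <- strsplit(lines[li], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L + nS)
      stop(sprintf("malformed VCF record at line %d: %d fields, expected %d",
                   li, length(f), 9L + nS))
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos)) stop(sprintf("malformed VCF record at line %d: bad POS", li))
    ref <- f[4]; alt <- f[5]
    if (!(ref %in% bases) || !(alt %in% bases) || grepl(",", alt, fixed = TRUE)) {
      n_skipped <- n_skipped + 1L
      next
    }
    keep_rows[[length(keep_rows) + 1L]] <- f
  }
  if (n_skipped > 0L)
    message(sprintf("read_vcf: skipped %d indel/multi-allelic records",
                    n_skipped))
  V <- length(keep_rows)
  if (V == 0L) stop("no biallelic SNP records in VCF")
  vt <- data.frame(
    chrom = vapply(keep_rows, `[`, "", 1L),
    pos = as.integer(vapply(keep_rows, `[`, "", 2L)),
    ref = vapply(keep_rows, `[`, "", 4L),
    alt = vapply(keep_rows, `[`, "", 5L), stringsAsFactors = FALSE)
  geno <- matrix(NA_integer_, nS, V, dimnames = list(samples, NULL))
  h1 <- matrix(NA_integer_, nS, V); h2 <- matrix(NA_integer_, nS, V)
  gp <- list(gp_rr = matrix(NA_real_, nS, V), gp_ra = matrix(NA_real_, nS, V),
             gp_aa = matrix(NA_real_, nS, V))
  ds <- matrix(NA_real_, nS, V)
  any_gp <- FALSE; any_ds <- FALSE; all_phased <- TRUE
  for (v in seq_len(V)) {
    f <- keep_rows[[v]]
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    i_gt <- match("GT", fmt); i_gp <- match("GP", fmt); i_ds <- match("DS", fmt)
    for (s in seq_len(nS)) {
      parts <- strsplit(f[9L + s], ":", fixed = TRUE)[[1]]
      if (!is.na(i_gt) && i_gt <= length(parts)) {
        g <- parts[i_gt]
        phased <- grepl("|", g, fixed = TRUE)
        if (!phased) all_phased <- FALSE
        al <- strsplit(g, "[/|]")[[1]]
        if (length(al) == 2L && !any(al == ".")) {
          a <- as.integer(al)
          geno[s, v] <- sum(a)
          if (phased) { h1[s, v] <- a[1]; h2[s, v] <- a[2] }
        }
      }
      if (!is.na(i_gp) && i_gp <= length(parts)) {
        trip <- suppressWarnings(
          as.numeric(strsplit(parts[i_gp], ",", fixed = TRUE)[[1]]))
        if (length(trip) == 3L && !anyNA(trip)) {
          gp$gp_rr[s, v] <- trip[1]; gp$gp_ra[s, v] <- trip[2]
          gp$gp_aa[s, v] <- trip[3]
          any_gp <- TRUE
        }
      }
      if (!is.na(i_ds) && i_ds <= length(parts)) {
        ds[s, v] <- suppressWarnings(as.numeric(parts[i_ds]))
        any_ds <- TRUE
      }
    }
  }
  haps <- NULL
  if (all_phased && !anyNA(h1)) {
    haps <- matrix(NA_integer_, 2L * nS, V)
    haps[2L * seq_len(nS) - 1L, ] <- h1
    haps[2L * seq_len(nS), ] <- h2
  }
  list(variant_table = vt, genotypes = geno,
       gp = if (any_gp) gp else NULL, dosage = if (any_ds) ds else NULL,
       haplotypes = haps, samples = samples, n_skipped = n_skipped)
}

#' Convert read VCF data to a haplotype panel
#'
#' @param vcf list from [read_vcf()] with phased haplotypes.
#' @param pop_label optional per-haplotype labels; defaults to the sample id
#'   repeated for its two haplotypes.
#' @return a [haplotype_panel()].
#' @export
vcf_as_panel <- function(vcf, pop_label = NULL) {
  if (is.null(vcf$haplotypes))
    stop("VCF is not fully phased; cannot build a haplotype panel")
  pop_label <- pop_label %||% rep(vcf$samples, each = 2L)
  haplotype_panel(vcf$haplotypes, vcf$variant_table, pop_label)
}

#' Write / read a read-count pileup TSV
#'
#' Columns: animal, chrom, pos, ref_count, alt_count.
#'
#' @param pileup a pileup data.table.
#' @param path file path.
#' @return `path` invisibly (write); the pileup data.table (read).
#' @export
write_pileup <- function(pileup, path) {
  data.table::fwrite(pileup, path, sep = "\t")
  invisible(path)
}

#' @rdname write_pileup
#' @export
read_pileup <- function(path) {
  pu <- data.table::fread(path, sep = "\t",
                          colClasses = list(character = c("animal", "chrom")))
  req <- c("animal", "chrom", "pos", "ref_count", "alt_count")
  if (!all(req %in% names(pu)))
    stop("pileup must have columns: ", paste(req, collapse = ", "))
  pu
}
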