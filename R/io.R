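#' Read genotype dosages from a VCF
#'
#' Parses a VCF 4.x file (via `vcfR`) into the dosage representation used
#' by the eQTL module. Per-sample dosage comes from the DS FORMAT field
#' when present, otherwise from the GT allele count. Multi-allelic
#' records are rejected and counted in the attached validation report.
#'
#' @param path VCF file (.vcf or .vcf.gz).
#' @return `genotype_matrix` list (variants, dosage, sample_ids) with a
#'   `report` attribute (n_records, n_rejected, offending lines).
#' @export
read_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix_raw <- vcfR::getFIX(vcf)
  if (is.null(dim(fix_raw))) fix_raw <- t(fix_raw)   # single-record VCF
  fix <- as.data.frame(fix_raw, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  report <- list(file = path, n_records = nrow(fix), n_rejected = sum(multi),
                 rejected = head(which(multi), 10),
                 reasons = rep("multi-allelic", min(10, sum(multi))))
  has_ds <- "DS" %in% vcfR::vcf_field_names(vcf, tag = "FORMAT")$ID
  if (has_ds) {
    dos <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    check_that(!is.null(gt), "VCF has neither DS nor GT")
    dos <- matrix(vapply(gt, function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]))
    }, numeric(1)), nrow = nrow(gt), dimnames = dimnames(gt))
  }
  keep <- !multi
  variants <- data.frame(variant_id = fix$ID[keep], chrom = fix$CHROM[keep],
                         pos = as.integer(fix$POS[keep]), ref = fix$REF[keep],
                         alt = fix$ALT[keep], stringsAsFactors = FALSE)
  dosage <- t(dos[keep, , drop = FALSE])
  colnames(dosage) <- variants$variant_id
  variants$maf <- pmin(colMeans(dosage) / 2, 1 - colMeans(dosage) / 2)
  out <- structure(list(variants = variants, dosage = dosage,
                        sample_ids = rownames(dosage)),
                   class = "genotype_matrix")
  attr(out, "report") <- report
  out
}

#' Write a genotype matrix as VCF 4.2
#'
#' Emits GT (rounded hard call) and DS (dosage) fields. Positions are
#' 1-based per the VCF convention.
#'
#' @param genotypes `genotype_matrix` list.
#' @param path output .vcf path (plain text).
#' @export
write_vcf <- function(genotypes, path) {
  v <- genotypes$variants
  d <- genotypes$dosage
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", genotypes$sample_ids), collapse = "\t"))
  gt_of <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(v)), function(i) {
    ds <- d[, i]
    cells <- paste0(gt_of[pmin(pmax(round(ds), 0), 2) + 1L], ":",
                    formatC(ds, format = "g"))
    paste(c(v$chrom[i], v$pos[i], v$variant_id[i], v$ref[i], v$alt[i],
            ".", "PASS", ".", "GT:DS", cells), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a chromatin-state segmentation (BED4)
#'
#' Columns: chrom, start, end, state; 0-based half-open intervals.
#' Intervals are sorted if needed (noted in the report); overlapping
#' intervals or end <= start are format errors. State labels are checked
#' against the configured vocabulary.
#'
#' @param path BED4 file.
#' @param vocabulary allowed state labels (default [chromatin_states()]).
#' @return data.frame chrom, start, end, state with a `report` attribute.
#' @export
read_bed_states <- function(path, vocabulary = chromatin_states()) {
  seg <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chrom", "start", "end", "state"))
  check_that(all(seg$end > seg$start),
             "BED intervals with end <= start in %s", path)
  bad <- setdiff(unique(seg$state), vocabulary)
  check_that(length(bad) == 0, "unknown state label(s) in %s: %s", path,
             paste(bad, collapse = ", "))
  note <- character(0)
  ord <- order(seg$chrom, seg$start)
  if (!identical(ord, seq_len(nrow(seg)))) {
    seg <- seg[ord, , drop = FALSE]
    note <- "input was unsorted; sorted on read"
  }
  by_chr <- split(seq_len(nrow(seg)), seg$chrom)
  for (idx in by_chr) {
    s <- seg[idx, , drop = FALSE]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)])) {
      stopf("overlapping intervals within %s in %s", s$chrom[1], path)
    }
  }
  rownames(seg) <- NULL
  attr(seg, "report") <- list(file = path, n_records = nrow(seg),
                              n_rejected = 0L, notes = note)
  seg
}

#' Write a segmentation or classified enhancer set as BED4
#'
#' @param seg data.frame chrom, start, end and a state/class column.
#' @param path output path.
#' @param name_col column written to the BED name field (default "state").
#' @export
write_bed_states <- function(seg, path, name_col = "state") {
  write.table(seg[, c("chrom", "start", "end", name_col)], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a TSV with the package dialect
#'
#' Tab-separated, mandatory header row, "." for missing values.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  data.table::setDF(data.table::fread(path, sep = "\t", header = TRUE,
                                      na.strings = ".", data.table = FALSE))
}

#' @rdname read_tsv
#' @param x data.frame to write.
#' @export
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", na = ".", quote = FALSE)
  invisible(path)
}

#' Write a gene x sample (or gene x tissue) matrix as TSV
#'
#' First column `gene_id`, remaining columns the matrix columns.
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
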