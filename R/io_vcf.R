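## VCF v4.2 and TSV input/output.
##
## Coordinates are 1-based GRCh37 throughout (VCF convention). The writer
## emits one multi-sample VCF with a GT field per patient; the reader
## (vcfR) decomposes multi-allelic records into biallelic rows before any
## filtering, since every rule is per alt allele.

#' Write a cohort to a multi-sample VCF v4.2
#'
#' One row per distinct variant, one sample column per patient, genotype
#' 0/1 for carriers and 0/0 otherwise.
#'
#' @param cohort A `prca_cohort` from [load_fixture_cohort()] or
#'   [simulate_cohort()].
#' @param path Output path (plain-text `.vcf`).
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(cohort, path) {
  v <- cohort$variants
  samples <- cohort$patients$patient_id
  ord <- order(v$chrom, v$pos, v$alt)
  v <- v[ord, , drop = FALSE]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=prcapanel",
    "##reference=GRCh37",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"HGNC gene symbol\">",
    "##INFO=<ID=CDNA,Number=1,Type=String,Description=\"HGVS cDNA change\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  carrier_of <- split(cohort$planted$patient_id, cohort$planted$key)
  rows <- vapply(seq_len(nrow(v)), function(i) {
    gt <- ifelse(samples %in% carrier_of[[v$key[i]]], "0/1", "0/0")
    id <- if ("dbsnp" %in% names(v) && !is.na(v$dbsnp[i])) v$dbsnp[i] else "."
    paste(c(v$chrom[i], v$pos[i], id, v$ref[i], v$alt[i], ".", "PASS",
            sprintf("GENE=%s;CDNA=%s", v$gene[i], v$cdna[i]), "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a VCF and join it with an annotation table
#'
#' Parses a VCF v4.2 (via vcfR), decomposes multi-allelic records into
#' biallelic rows, extracts per-sample genotypes, and (optionally) joins
#' the variants with an annotation table by (chrom, pos, ref, alt). Join
#' failures are reported with a warning, never dropped silently.
#'
#' @param path Path to a VCF file.
#' @param annotations Optional annotation table (data frame or path to a
#'   TSV in the [annotation_columns()] dialect).
#' @return List with `variants` (one row per biallelic variant; annotation
#'   columns appended when supplied) and `genotypes` (`patient_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `gt` for every non-reference call).
#' @export
read_vcf <- function(path, annotations = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix)))   # single-record VCFs drop to a named vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (!nrow(fix)) {
    empty <- data.frame(chrom = character(), pos = integer(),
                        id = character(), ref = character(),
                        alt = character(), stringsAsFactors = FALSE)
    return(list(variants = empty,
                genotypes = data.frame(patient_id = character(),
                                       chrom = character(), pos = integer(),
                                       ref = character(), alt = character(),
                                       gt = character())))
  }
  gt <- if (ncol(vcf@gt) > 1) vcfR::extract.gt(vcf, "GT") else NULL

  rows <- list(); genos <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (j in seq_along(alts)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        id = ifelse(is.na(fix$ID[i]), ".", fix$ID[i]),
        ref = fix$REF[i], alt = alts[j], stringsAsFactors = FALSE)
      if (!is.null(gt)) {
        g <- gt[i, ]
        has_alt <- vapply(strsplit(ifelse(is.na(g), "0/0", g), "[/|]"),
                          function(a) as.character(j) %in% a, TRUE)
        if (any(has_alt)) {
          genos[[length(genos) + 1L]] <- data.frame(
            patient_id = colnames(gt)[has_alt],
            chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
            ref = fix$REF[i], alt = alts[j],
            gt = unname(g[has_alt]), stringsAsFactors = FALSE)
        }
      }
    }
  }
  variants <- do.call(rbind, rows)
  genotypes <- if (length(genos)) do.call(rbind, genos)
               else data.frame(patient_id = character(), chrom = character(),
                               pos = integer(), ref = character(),
                               alt = character(), gt = character())
  rownames(variants) <- rownames(genotypes) <- NULL

  if (!is.null(annotations)) {
    ann <- if (is.character(annotations)) read_tsv_dot(annotations)
           else annotations
    key_v <- paste(variants$chrom, variants$pos, variants$ref, variants$alt)
    key_a <- paste(ann$chrom, ann$pos, ann$ref, ann$alt)
    idx <- match(key_v, key_a)
    if (anyNA(idx))
      warnf("%d variant(s) have no annotation row: %s", sum(is.na(idx)),
            paste(utils::head(key_v[is.na(idx)], 5), collapse = "; "))
    extra <- ann[idx, setdiff(names(ann), c("chrom", "pos", "ref", "alt")),
                 drop = FALSE]
    rownames(extra) <- NULL
    variants <- cbind(variants, extra)
  }
  list(variants = variants, genotypes = genotypes)
}

#' Write a cohort's tables to a directory
#'
#' Emits the multi-sample VCF, the annotation TSV (one row per distinct
#' variant), the per-patient planted-variant TSV, the patient metadata TSV
#' (with relatives and second primaries) and the control-counts TSV.
#'
#' @param cohort A `prca_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort_vcf(cohort, file.path(dir, "cohort.vcf"))
  write_tsv_dot(cohort$variants, file.path(dir, "annotations.tsv"))
  write_tsv_dot(cohort$planted, file.path(dir, "planted.tsv"))
  write_tsv_dot(cohort$patients, file.path(dir, "patients.tsv"))
  write_tsv_dot(cohort$relatives, file.path(dir, "relatives.tsv"))
  if (!is.null(cohort$second_primaries) && nrow(cohort$second_primaries))
    write_tsv_dot(cohort$second_primaries,
                  file.path(dir, "second_primaries.tsv"))
  write_tsv_dot(cohort$controls, file.path(dir, "controls.tsv"))
  invisible(dir)
}
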