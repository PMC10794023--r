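#' Write a unified call set as tab-separated text
#'
#' Extended SMAP-like layout: one row per call with columns `call_id`,
#' `type`, `ref_id`, `start`, `end`, `size`, `zygosity`, `allele_fraction`,
#' `support`, `status`, `confidence` (plus `pipeline`, `genes`, `cross_ref`
#' when present).
#'
#' @param calls data.table from [annotate_and_deduplicate()] or
#'   [call_indels()].
#' @param path output path.
#' @export
write_calls_tsv <- function(calls, path) {
  ct <- data.table::as.data.table(calls)
  ren <- c(sv_type = "type", start_bp = "start", end_bp = "end",
           size_bp = "size")
  for (nm in names(ren)) {
    if (nm %in% names(ct)) data.table::setnames(ct, nm, ren[[nm]])
  }
  first <- intersect(c("call_id", "type", "ref_id", "start", "end", "size",
                       "zygosity", "allele_fraction", "support", "status",
                       "confidence"), names(ct))
  data.table::setcolorder(ct, first)
  data.table::fwrite(ct, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a call set written by [write_calls_tsv()]
#'
#' @param path file path.
#' @return data.table with the package-internal column names.
#' @export
read_calls_tsv <- function(path) {
  ct <- data.table::fread(path, sep = "\t", na.strings = "NA",
                          colClasses = list(character = "ref_id"))
  ren <- c(type = "sv_type", start = "start_bp", end = "end_bp",
           size = "size_bp")
  for (nm in names(ren)) {
    if (nm %in% names(ct)) data.table::setnames(ct, nm, ren[[nm]])
  }
  ct
}

#' Write calls as minimal VCF 4.2 with symbolic alleles
#'
#' Insertions, deletions, inversions and duplications are emitted as
#' symbolic-ALT records (`<INS>`, `<DEL>`, `<INV>`, `<DUP>`) with `SVTYPE`,
#' `END`, `SVLEN`, `SUPPORT` and `AF` INFO fields; translocations as a pair
#' of `BND` break-end records with mate coordinates. Positions are rounded
#' to integer bp (label resolution is coarser than 1 bp anyway) and REF
#' bases are reported as `N` (label maps carry no sequence).
#'
#' @param calls unified call table ([annotate_and_deduplicate()] output).
#' @param path output path.
#' @param ref_genome named list of reference [label_map()] for contig
#'   headers.
#' @export
write_calls_vcf <- function(calls, path, ref_genome = NULL) {
  ct <- data.table::as.data.table(calls)
  con <- file(path, open = "wt")
  on.exit(close(con))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=omapsv",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Supporting molecules\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele fraction\">",
    "##INFO=<ID=STATUS,Number=1,Type=String,Description=\"Break-point completeness\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate break-end\">",
    "##ALT=<ID=INS,Description=\"Insertion\">",
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=INV,Description=\"Inversion\">",
    "##ALT=<ID=DUP,Description=\"Duplication\">")
  if (!is.null(ref_genome)) {
    hdr <- c(hdr, vapply(ref_genome, function(m)
      sprintf("##contig=<ID=%s,length=%d>", m$map_id,
              as.integer(ceiling(m$length_bp))), character(1)))
  }
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  writeLines(hdr, con)
  sym <- c(insertion = "INS", deletion = "DEL", inversion = "INV",
           duplication = "DUP")
  for (i in seq_len(nrow(ct))) {
    ty <- ct$sv_type[i]
    common <- sprintf("SUPPORT=%d%s%s",
                      as.integer(round(ct$support[i])),
                      if (!is.null(ct$allele_fraction) &&
                          !is.na(ct$allele_fraction[i]))
                        sprintf(";AF=%.4f", ct$allele_fraction[i]) else "",
                      if (!is.null(ct$status) && !is.na(ct$status[i]))
                        sprintf(";STATUS=%s", ct$status[i]) else "")
    if (ty %in% names(sym)) {
      svlen <- as.integer(round(ct$size_bp[i])) *
        if (ty == "deletion") -1L else 1L
      writeLines(sprintf(
        "%s\t%d\t%s\tN\t<%s>\t.\tPASS\tSVTYPE=%s;END=%d;SVLEN=%d;%s",
        ct$ref_id[i], as.integer(round(ct$start_bp[i])), ct$call_id[i],
        sym[[ty]], sym[[ty]], as.integer(round(ct$end_bp[i])), svlen,
        common), con)
    } else { # translocations as a BND pair
      chr2 <- if (!is.null(ct$ref_id2) && !is.na(ct$ref_id2[i]))
        ct$ref_id2[i] else ct$ref_id[i]
      pos2 <- if (!is.null(ct$pos2_bp) && !is.na(ct$pos2_bp[i]))
        ct$pos2_bp[i] else ct$end_bp[i]
      id_a <- paste0(ct$call_id[i], "_bnd1")
      id_b <- paste0(ct$call_id[i], "_bnd2")
      writeLines(sprintf(
        "%s\t%d\t%s\tN\tN[%s:%d[\t.\tPASS\tSVTYPE=BND;MATEID=%s;%s",
        ct$ref_id[i], as.integer(round(ct$start_bp[i])), id_a,
        chr2, as.integer(round(pos2)), id_b, common), con)
      writeLines(sprintf(
        "%s\t%d\t%s\tN\t]%s:%d]N\t.\tPASS\tSVTYPE=BND;MATEID=%s;%s",
        chr2, as.integer(round(pos2)), id_b,
        ct$ref_id[i], as.integer(round(ct$start_bp[i])), id_a, common), con)
    }
  }
  invisible(path)
}

#' Write a truth table as tab-separated text
#'
#' @param truth [truth_table()] output (optionally with empirical columns).
#' @param path output path.
#' @export
write_truth_tsv <- function(truth, path) {
  data.table::fwrite(data.table::as.data.table(truth), path, sep = "\t",
                     na = "NA", quote = FALSE)
  invisible(path)
}
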