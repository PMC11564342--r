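# Columns of a somatic-call table (MAF-like dialect used throughout the
# pipeline). `normal_vaf` is optional and only required for plasma-mode
# consensus filtering.
.call_columns <- c(
  "patient_id", "sample_type", "chrom", "pos", "ref", "alt", "caller",
  "vaf", "depth", "alt_reads", "pop_af_1kg", "pop_af_exac", "mappability",
  "gene", "variant_class", "protein_change"
)

.sample_types <- c("tissue", "plasma")
.variant_classes <- c("missense", "nonsense", "frameshift", "splice",
                      "synonymous", "intron", "other")

#' Construct and validate a somatic-call table
#'
#' A somatic call is one caller's record of one candidate mutation in one
#' sample, with its annotations (VAF, depth, population allele frequencies,
#' mappability). Several callers' records for the same allele are distinct
#' rows distinguished by the `caller` tag.
#'
#' @param df data.frame with at least the columns listed in Details.
#'   Missing annotation columns (`pop_af_1kg`, `pop_af_exac`, `mappability`,
#'   `gene`, `variant_class`, `protein_change`) are added as `NA`; they are
#'   never zero-filled.
#' @return the validated data.frame with class `somatic_calls` prepended.
#' @details Required columns: `patient_id`, `sample_type` (tissue/plasma),
#'   `chrom`, `pos` (1-based), `ref`, `alt`, `caller`, `vaf`, `depth`,
#'   `alt_reads`. Invariants checked per row: `pos >= 1`, `ref != alt`,
#'   `alt_reads <= depth`, and when vaf/depth/alt_reads are all present,
#'   `|vaf - alt_reads/depth| <= 1/depth`.
#' @export
somatic_calls <- function(df) {
  stopifnot(is.data.frame(df))
  required <- c("patient_id", "sample_type", "chrom", "pos", "ref", "alt",
                "caller", "vaf", "depth", "alt_reads")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("missing required call columns: ", paste(miss, collapse = ", "))
  for (col in setdiff(.call_columns, names(df))) df[[col]] <- NA
  df$pos <- as.integer(df$pos)
  df$depth <- as.integer(df$depth)
  df$alt_reads <- as.integer(df$alt_reads)
  df$ref <- toupper(as.character(df$ref))
  df$alt <- toupper(as.character(df$alt))
  .validate_calls(df)
  df <- df[, union(.call_columns, names(df)), drop = FALSE]
  class(df) <- unique(c("somatic_calls", class(df)))
  df
}

.validate_calls <- function(df, line_offset = 0L) {
  bad <- function(cond, what) {
    idx <- which(cond)
    if (length(idx))
      stop(sprintf("invalid call record(s) at line %s: %s",
                   paste(idx + line_offset, collapse = ","), what),
           call. = FALSE)
  }
  bad(!(df$sample_type %in% .sample_types), "sample_type must be tissue or plasma")
  bad(is.na(df$pos) | df$pos < 1L, "pos must be >= 1")
  bad(df$ref == df$alt, "ref must differ from alt")
  bad(!is.na(df$alt_reads) & !is.na(df$depth) & df$alt_reads > df$depth,
      "alt_reads > depth")
  bad(!is.na(df$depth) & df$depth < 0L, "negative depth")
  ok <- !is.na(df$vaf) & !is.na(df$depth) & !is.na(df$alt_reads) & df$depth > 0L
  bad(ok & abs(df$vaf - df$alt_reads / df$depth) > 1 / df$depth + 1e-9,
      "vaf inconsistent with alt_reads/depth")
  if ("variant_class" %in% names(df))
    bad(!is.na(df$variant_class) & !(df$variant_class %in% .variant_classes),
        paste("variant_class must be one of:",
              paste(.variant_classes, collapse = ", ")))
  invisible(df)
}

#' Read somatic calls from VCF or MAF-like TSV
#'
#' @param path input file.
#' @param format `"maf"` (tab-separated, columns as in [somatic_calls()]) or
#'   `"vcf"` (VCF 4.x, single-sample; positions are 1-based).
#' @param patient_id,sample_type,caller defaults used for VCF input, where
#'   these fields are not part of the record (a `CALLER` INFO key overrides
#'   `caller`).
#' @return a `somatic_calls` data.frame, one row per record per caller tag.
#'   Missing annotations are `NA`.
#' @export
read_calls <- function(path, format = c("maf", "vcf"), patient_id = "sample",
                       sample_type = "tissue", caller = "unknown") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "maf") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            na.strings = c("NA", "", "."))
    .validate_calls(df, line_offset = 1L)  # report file line numbers
    return(somatic_calls(df))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  grab <- function(key) suppressWarnings(vcfR::extract.info(v, key))
  num <- function(x) suppressWarnings(as.numeric(x))
  dp <- num(grab("DP"))
  af <- num(grab("AF"))
  ao <- num(grab("AO"))
  tag <- grab("CALLER")
  alt_reads <- ifelse(!is.na(ao), ao, ifelse(!is.na(af) & !is.na(dp),
                                             round(af * dp), NA))
  somatic_calls(data.frame(
    patient_id = patient_id, sample_type = sample_type,
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    caller = ifelse(is.na(tag) | !nzchar(tag), caller, tag),
    vaf = af, depth = as.integer(dp), alt_reads = as.integer(alt_reads),
    stringsAsFactors = FALSE
  ))
}

#' Write somatic calls as a MAF-like TSV
#'
#' @param calls a `somatic_calls` data.frame.
#' @param path output file.
#' @export
write_maf <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Variant keys: normalized allele identities
#'
#' Builds `chrom:pos:ref>alt` identifier strings. Two keys are equal iff the
#' records denote the same allele, provided both were normalized with
#' [normalize_variant()] first.
#'
#' @param chrom,pos,ref,alt allele components (vectors recycled as usual).
#' @return character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  sprintf("%s:%d:%s>%s", chrom, as.integer(pos), ref, alt)
}

.ref_fetch <- function(reference, chrom, start, end) {
  if (inherits(reference, "DNAStringSet") || inherits(reference, "XStringSet")) {
    if (!(chrom %in% names(reference))) stop("reference lacks chromosome ", chrom)
    seq <- reference[[chrom]]
    if (end > length(seq) || start < 1L) stop("locus outside reference: ",
                                             chrom, ":", start, "-", end)
    return(as.character(Biostrings::subseq(seq, start, end)))
  }
  if (is.character(reference)) {
    if (!(chrom %in% names(reference))) stop("reference lacks chromosome ", chrom)
    if (end > nchar(reference[[chrom]]) || start < 1L)
      stop("locus outside reference: ", chrom, ":", start, "-", end)
    return(substr(reference[[chrom]], start, end))
  }
  stop("reference must be a named character vector or DNAStringSet")
}

#' Normalize a variant to its left-aligned minimal representation
#'
#' Indels called by different tools can be spelled at different positions in
#' repetitive sequence. Normalization trims shared flanking bases and shifts
#' the allele as far left as possible, so that equivalent spellings map to
#' one [variant_key()]. The operation is idempotent.
#'
#' @param chrom,pos,ref,alt the variant (1-based, uppercase alleles).
#' @param reference named character vector or `Biostrings::DNAStringSet`
#'   keyed by chromosome; must cover the locus and agree with `ref`.
#' @return list with `chrom`, `pos`, `ref`, `alt`, `key`.
#' @export
normalize_variant <- function(chrom, pos, ref, alt, reference) {
  pos <- as.integer(pos)
  ref <- toupper(ref); alt <- toupper(alt)
  if (ref == alt) stop("ref equals alt")
  obs <- .ref_fetch(reference, chrom, pos, pos + nchar(ref) - 1L)
  if (!identical(obs, ref))
    stop(sprintf("ref allele mismatch at %s:%d: call says %s, reference has %s",
                 chrom, pos, ref, obs))
  last <- function(x) substr(x, nchar(x), nchar(x))
  # right-trim shared suffix, extending left through repeats
  repeat {
    if (nchar(ref) > 0 && nchar(alt) > 0 && last(ref) == last(alt)) {
      ref <- substr(ref, 1L, nchar(ref) - 1L)
      alt <- substr(alt, 1L, nchar(alt) - 1L)
      if (nchar(ref) == 0L || nchar(alt) == 0L) {
        if (pos == 1L) {  # cannot extend left; re-anchor on the right instead
          base <- .ref_fetch(reference, chrom, pos + nchar(ref), pos + nchar(ref))
          ref <- paste0(ref, base); alt <- paste0(alt, base)
          break
        }
        pos <- pos - 1L
        base <- .ref_fetch(reference, chrom, pos, pos)
        ref <- paste0(base, ref); alt <- paste0(base, alt)
      }
    } else break
  }
  # left-trim shared prefix while both alleles keep >= 1 base
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(chrom = chrom, pos = pos, ref = ref, alt = alt,
       key = variant_key(chrom, pos, ref, alt))
}

#' Normalize every call in a table and attach keys
#'
#' @param calls `somatic_calls` data.frame.
#' @param reference as in [normalize_variant()]. When `NULL`, SNVs are keyed
#'   as-is (they are already minimal) and indels raise an error.
#' @return `calls` with columns `pos`, `ref`, `alt` normalized and a new
#'   `key` column.
#' @export
normalize_calls <- function(calls, reference = NULL) {
  if (is.null(reference)) {
    indel <- nchar(calls$ref) != 1L | nchar(calls$alt) != 1L
    if (any(indel))
      stop("indel normalization requires a reference sequence")
    calls$key <- variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
    return(calls)
  }
  out <- lapply(seq_len(nrow(calls)), function(i)
    normalize_variant(calls$chrom[i], calls$pos[i], calls$ref[i],
                      calls$alt[i], reference))
  calls$pos <- vapply(out, `[[`, integer(1), "pos")
  calls$ref <- vapply(out, `[[`, character(1), "ref")
  calls$alt <- vapply(out, `[[`, character(1), "alt")
  calls$key <- vapply(out, `[[`, character(1), "key")
  calls
}

#' Read / write allele-specific copy-number segments (SEG-style TSV)
#'
#' File columns: `sample` (optional), `chrom`, `start`, `end` (1-based
#' inclusive on disk), `total_cn`, `minor_cn`. Internally coordinates are
#' 0-based half-open; [write_segments()] converts back.
#'
#' @param path TSV file.
#' @return data.frame of class `cn_segments` with 0-based half-open
#'   `start`/`end`.
#' @export
read_segments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "total_cn", "minor_cn")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("segment file lacks columns: ", paste(miss, collapse = ", "))
  if (!("sample" %in% names(df))) df$sample <- "sample"
  df$start <- as.numeric(df$start) - 1  # to 0-based half-open
  df$end <- as.numeric(df$end)
  cn_segments(df)
}

#' @rdname read_segments
#' @param df segment data.frame (0-based half-open coordinates).
#' @export
cn_segments <- function(df) {
  stopifnot(all(c("sample", "chrom", "start", "end", "total_cn", "minor_cn")
                %in% names(df)))
  if (any(df$end <= df$start)) stop("segment with end <= start")
  if (any(df$total_cn < 0 | df$minor_cn < 0)) stop("negative copy number")
  if (any(df$minor_cn > floor(df$total_cn / 2)))
    stop("minor_cn exceeds total_cn/2")
  for (grp in split(df, paste(df$sample, df$chrom))) {
    o <- order(grp$start)
    if (nrow(grp) > 1 && any(grp$start[o][-1] < grp$end[o][-nrow(grp)]))
      stop("overlapping segments on ", grp$chrom[1], " for sample ",
           grp$sample[1])
  }
  class(df) <- unique(c("cn_segments", class(df)))
  df
}

#' @rdname read_segments
#' @param segments `cn_segments` data.frame.
#' @export
write_segments <- function(segments, path) {
  out <- as.data.frame(segments)
  out$start <- out$start + 1  # back to 1-based inclusive
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Binary gene-by-patient mutation matrix with cohort labels
#'
#' @param mat integer/logical matrix, genes in rows (rownames = gene
#'   symbols), patients in columns (colnames = patient ids), entries 0/1.
#' @param cohort named character vector (one label per patient), e.g.
#'   `"CRA"`, `"CRC-I"`, `"CRC-IV"`, `"FAP-MAP"`, `"mCRC-plasma"`.
#' @param outcome optional named character vector per patient
#'   (`"polyp-free"`, `"persistent"`, `"cancerous"`).
#' @return object of class `gene_matrix`.
#' @export
gene_matrix <- function(mat, cohort, outcome = NULL) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "integer"
  if (!all(mat %in% c(0L, 1L))) stop("matrix entries must be 0/1")
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("matrix needs gene rownames and patient colnames")
  if (is.null(names(cohort))) names(cohort) <- colnames(mat)
  if (!all(colnames(mat) %in% names(cohort)))
    stop("cohort labels must cover every patient")
  cohort <- cohort[colnames(mat)]
  if (!is.null(outcome)) outcome <- outcome[colnames(mat)]
  structure(list(mat = mat, cohort = cohort, outcome = outcome),
            class = "gene_matrix")
}

#' @export
print.gene_matrix <- function(x, ...) {
  cat("gene_matrix:", nrow(x$mat), "genes x", ncol(x$mat), "patients\n")
  print(table(x$cohort))
  invisible(x)
}

#' Read / write a gene-by-patient matrix TSV
#'
#' The matrix file has a `gene` column followed by one 0/1 column per
#' patient. Labels live in a second TSV with columns `patient`, `cohort`
#' and optionally `outcome`.
#'
#' @param path matrix TSV.
#' @param labels_path labels TSV (optional; all patients labelled
#'   `"unknown"` when absent).
#' @return a [gene_matrix()].
#' @export
read_gene_matrix <- function(path, labels_path = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "gene") stop("first column of matrix file must be 'gene'")
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$gene
  if (!is.null(labels_path)) {
    lab <- utils::read.delim(labels_path, stringsAsFactors = FALSE)
    cohort <- stats::setNames(lab$cohort, lab$patient)
    outcome <- if ("outcome" %in% names(lab))
      stats::setNames(lab$outcome, lab$patient) else NULL
  } else {
    cohort <- stats::setNames(rep("unknown", ncol(mat)), colnames(mat))
    outcome <- NULL
  }
  gene_matrix(mat, cohort, outcome)
}

#' @rdname read_gene_matrix
#' @param gm a [gene_matrix()].
#' @param labels_path_out optional path for the labels TSV.
#' @export
write_gene_matrix <- function(gm, path, labels_path_out = NULL) {
  df <- data.frame(gene = rownames(gm$mat), gm$mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(labels_path_out)) {
    lab <- data.frame(patient = colnames(gm$mat), cohort = unname(gm$cohort))
    if (!is.null(gm$outcome)) lab$outcome <- unname(gm$outcome)
    utils::write.table(lab, labels_path_out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
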