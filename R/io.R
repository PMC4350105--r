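#' @importFrom rtracklayer import export
NULL

#' Read a bin-level methylation track from bedGraph
#'
#' Records must be aligned to the fixed bin grid: start and end of every
#' record are multiples of `binWidth` (bins a record spans all receive
#' its value). Absent bins are 0.
#'
#' @param path bedGraph file (chrom, start, end, value; 0-based
#'   half-open, as the format specifies).
#' @param binWidth bin width in bp.
#' @param chromLengths optional named vector of chromosome lengths; when
#'   omitted, each chromosome extends to the last observed record.
#' @return named list of per-chromosome numeric vectors (one entry per
#'   bin), with attributes `binWidth`.
#' @export
readBinTrack <- function(path, binWidth = 100L, chromLengths = NULL) {
  binWidth <- as.integer(binWidth)
  df <- tryCatch(
    utils::read.table(path, header = FALSE, sep = "", comment.char = "#",
                      col.names = c("chrom", "start", "end", "value"),
                      colClasses = c("character", "integer", "integer",
                                     "numeric")),
    error = function(e) {
      if (length(readLines(path, n = 1)) == 0L) NULL else stop(e)
    })
  if (is.null(df) || nrow(df) == 0L) {
    warning("empty bedGraph: ", path)
    df <- data.frame(chrom = character(), start = integer(),
                     end = integer(), value = numeric())
  }
  bad <- which(df$start %% binWidth != 0L | df$end %% binWidth != 0L |
                 df$end <= df$start)
  if (length(bad))
    stop(sprintf("record not aligned to the %d-bp bin grid at line %d of %s",
                 binWidth, bad[1], path))
  if (any(df$value < 0))
    stop(sprintf("negative value at line %d of %s",
                 which(df$value < 0)[1], path))
  chroms <- if (!is.null(chromLengths)) names(chromLengths)
            else sort(unique(df$chrom))
  vals <- lapply(chroms, function(ch) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    len <- if (!is.null(chromLengths)) chromLengths[[ch]]
           else if (nrow(sub)) max(sub$end) else 0L
    v <- numeric(ceiling(len / binWidth))
    if (nrow(sub)) {
      for (i in seq_len(nrow(sub))) {
        idx <- (sub$start[i] %/% binWidth + 1L):(sub$end[i] %/% binWidth)
        v[idx] <- sub$value[i]
      }
    }
    v
  })
  names(vals) <- chroms
  structure(vals, binWidth = binWidth)
}

#' Write a bin-level track as bedGraph
#'
#' Zero bins are omitted (bedGraph is sparse); [readBinTrack()] restores
#' them, making write-then-read an identity.
#'
#' @param values named list of per-chromosome bin-value vectors.
#' @param path output file.
#' @param binWidth bin width in bp.
#' @export
writeBinTrack <- function(values, path, binWidth = 100L) {
  binWidth <- as.integer(binWidth)
  rows <- lapply(names(values), function(ch) {
    v <- values[[ch]]
    nz <- which(v != 0)
    if (!length(nz)) return(NULL)
    data.frame(chrom = ch, start = (nz - 1L) * binWidth,
               end = nz * binWidth, value = v[nz])
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame()
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Assemble a cohort BinMethylome from a sample manifest
#'
#' @param manifest data.frame with columns `sample_id`, `group`
#'   (`tumor`/`normal`) and `path` (bedGraph per sample). Sample ids must
#'   be unique and each group must have >= 2 samples.
#' @param binWidth bin width in bp.
#' @param chromLengths named vector of chromosome lengths (required so
#'   that all samples share one grid).
#' @return a [BinMethylome-class].
#' @export
readBinTracks <- function(manifest, binWidth = 100L, chromLengths) {
  stopifnot(all(c("sample_id", "group", "path") %in% names(manifest)))
  if (anyDuplicated(manifest$sample_id))
    stop("duplicate sample_id in manifest")
  if (any(table(factor(manifest$group, c("tumor", "normal"))) < 2L))
    stop("need >= 2 samples per group")
  tracks <- lapply(manifest$path, readBinTrack, binWidth = binWidth,
                   chromLengths = chromLengths)
  counts <- vapply(tracks, function(t) unlist(t, use.names = FALSE),
                   numeric(sum(ceiling(chromLengths / binWidth))))
  bins <- binGrid(chromLengths, binWidth)
  BinMethylome(counts, bins, manifest$group, binWidth,
               sampleIds = manifest$sample_id)
}

# The full genome bin grid as a GRanges, chromosome by chromosome.
binGrid <- function(chromLengths, binWidth = 100L) {
  binWidth <- as.integer(binWidth)
  nBins <- as.integer(ceiling(chromLengths / binWidth))
  starts <- unlist(lapply(nBins, function(n)
    seq_len(n) * binWidth - binWidth + 1L), use.names = FALSE)
  GRanges(rep(names(chromLengths), nBins), IRanges(starts, width = binWidth))
}

#' Read a gene annotation
#'
#' Two supported formats. `bed12`: BED12 with one extra column holding
#' the gene class (`coding`, `lncRNA`, `miRNA`); the BED name field is
#' the gene id. `gtf_lite`: GTF `gene` records with `gene_id` and
#' `gene_class` attributes; 1-based starts are converted to the in-memory
#' convention on import.
#'
#' @param path annotation file.
#' @param format `"bed12"` or `"gtf_lite"`.
#' @return [GenomicRanges::GRanges] with `gene_id` and `gene_class`
#'   metadata columns.
#' @export
readAnnotation <- function(path, format = c("bed12", "gtf_lite")) {
  format <- match.arg(format)
  if (format == "bed12") {
    gr <- rtracklayer::import(path, format = "bed",
                              extraCols = c(gene_class = "character"))
    mcols(gr) <- DataFrame(gene_id = mcols(gr)$name,
                           gene_class = mcols(gr)$gene_class)
  } else {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[mcols(gr)$type == "gene"]
    mcols(gr) <- DataFrame(gene_id = mcols(gr)$gene_id,
                           gene_class = mcols(gr)$gene_class)
  }
  if (any(is.na(mcols(gr)$gene_class)) ||
      !all(mcols(gr)$gene_class %in% c("coding", "lncRNA", "miRNA")))
    stop("unknown gene_class (expected coding/lncRNA/miRNA)")
  if (anyDuplicated(mcols(gr)$gene_id))
    stop("duplicate gene_id: ",
         mcols(gr)$gene_id[duplicated(mcols(gr)$gene_id)][1])
  gr
}

#' Read a plain region set (CGIs, polycomb domains, deletion regions)
#'
#' @param path BED file.
#' @return unstranded [GenomicRanges::GRanges]; the BED name column, if
#'   present, is kept as `region_id`.
#' @export
readRegionsBed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  strand(gr) <- "*"
  nm <- mcols(gr)$name
  mcols(gr) <- NULL
  if (!is.null(nm)) mcols(gr)$region_id <- nm
  gr
}

#' Read an expression table
#'
#' @param path TSV with a header of sample ids and gene ids in the first
#'   column.
#' @param kind `"fpkm_cell_lines"` (lncRNA FPKM per cell line) or
#'   `"rpm_cohort"` (miRNA RPM per cohort sample); both are validated the
#'   same way, the kind is recorded as an attribute.
#' @return numeric matrix, genes x samples.
#' @export
readExpressionTable <- function(path, kind = c("fpkm_cell_lines", "rpm_cohort")) {
  kind <- match.arg(kind)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (anyDuplicated(df[[1]]))
    stop("duplicated gene row: ", df[[1]][duplicated(df[[1]])][1])
  ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(apply(m, 2L, as.numeric))
  if (!is.matrix(num)) num <- matrix(num, nrow = nrow(m), dimnames = dimnames(m))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric or missing cell at gene '%s', sample '%s'",
                 ids[bad[1, 1]], colnames(m)[bad[1, 2]]))
  rownames(num) <- ids
  structure(num, kind = kind)
}

#' Write DMRs as BED6+3
#'
#' Columns: chrom, start, end, name, score = -log10(min adjusted p)
#' capped at 300, strand ".", then direction, n_bins and the maximal
#' absolute log2 fold change. Output is sorted by (chrom, start).
#'
#' @param dmrs [GenomicRanges::GRanges] from [mergeBinsToDmrs()].
#' @param path output file.
#' @export
writeDmrBed <- function(dmrs, path) {
  if (length(dmrs)) {
    dmrs <- dmrs[order(as.character(seqnames(dmrs)), start(dmrs))]
    score <- pmin(300, -log10(pmax(mcols(dmrs)$min_q, 1e-300)))
    df <- data.frame(chrom = as.character(seqnames(dmrs)),
                     start = start(dmrs) - 1L, end = end(dmrs),
                     name = sprintf("dmr_%d", seq_along(dmrs)),
                     score = score, strand = ".",
                     direction = as.character(mcols(dmrs)$direction),
                     n_bins = mcols(dmrs)$n_bins,
                     max_abs_l2fc = mcols(dmrs)$max_abs_l2fc)
  } else df <- data.frame()
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read DMRs written by [writeDmrBed()]
#'
#' @param path BED6+3 file.
#' @return [GenomicRanges::GRanges] with `direction`, `n_bins`, `min_q`
#'   (recovered from the score up to the 300 cap) and `max_abs_l2fc`.
#' @export
readDmrBed <- function(path) {
  if (length(readLines(path, n = 1)) == 0L)
    return(emptyDmrGRanges())
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand", "direction",
                                        "n_bins", "max_abs_l2fc"))
  GRanges(df$chrom, IRanges(df$start + 1L, df$end),
          direction = factor(df$direction, c("hyper", "hypo")),
          n_bins = df$n_bins, min_q = 10^(-df$score),
          max_abs_l2fc = df$max_abs_l2fc)
}
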