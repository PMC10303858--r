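#' Read a BED6(+3) file of genomic intervals or L1 loci
#'
#' Parses tab-separated BED with 3, 6 or 9 columns. BED coordinates are
#' 0-based half-open and are converted to the 1-based inclusive `GRanges`
#' convention on read (the writers convert back, so round trips are
#' exact). When the three extra RepeatMasker-style columns are present
#' they are mapped to `subfamily`, `milliDiv` and checked against the
#' interval length. The subfamily of an id such as `"L1PA7:L1:LINE"` is
#' its first colon-separated token.
#'
#' @param path BED file path.
#' @return a `GRanges`, named by the BED name column when present, with
#'   metadata columns `score` (and `subfamily`, `milliDiv` for BED6+3).
#' @export
readBed <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          colClasses = list(character = 1), fill = FALSE,
                          data.table = TRUE)
  nc <- ncol(dt)
  if (!nc %in% c(3L, 4L, 6L, 9L))
    stop("BED file must have 3, 4, 6 or 9 tab-separated columns, found ", nc)
  start0 <- suppressWarnings(as.numeric(dt[[2]]))
  end0 <- suppressWarnings(as.numeric(dt[[3]]))
  bad <- which(!is.finite(start0) | !is.finite(end0) |
                 start0 != floor(start0) | end0 != floor(end0))
  if (length(bad))
    stop("non-integer coordinates at line ", bad[1], " of ", path)
  bad <- which(start0 >= end0 | start0 < 0)
  if (length(bad))
    stop(sprintf("invalid interval (start >= end or start < 0) at line %d of %s",
                 bad[1], path))
  strand <- if (nc >= 6L) dt[[6]] else "*"
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- grFrom(dt[[1]], start0 + 1, end0, strand = strand)
  if (nc >= 4L) names(gr) <- dt[[4]]
  if (nc >= 6L) S4Vectors::mcols(gr)$score <- suppressWarnings(as.numeric(dt[[5]]))
  if (nc == 9L) {
    S4Vectors::mcols(gr)$subfamily <- dt[[7]]
    S4Vectors::mcols(gr)$milliDiv <- suppressWarnings(as.numeric(dt[[8]]))
    len <- suppressWarnings(as.integer(dt[[9]]))
    if (any(len != GenomicRanges::width(gr)))
      stop("length column disagrees with end - start in ", path)
  }
  gr
}

#' @rdname readBed
#' @param gr a `GRanges`; when `subfamily`/`milliDiv` metadata columns are
#'   present a BED6+3 file is written, otherwise BED6.
#' @param path output path.
#' @export
writeBed <- function(gr, path) {
  mc <- S4Vectors::mcols(gr)
  score <- if ("score" %in% colnames(mc)) mc$score else 0
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (is.null(names(gr))) "." else names(gr),
    score = score, strand = strand)
  if (all(c("subfamily", "milliDiv") %in% colnames(mc))) {
    dt$subfamily <- mc$subfamily
    dt$milliDiv <- mc$milliDiv
    dt$length <- GenomicRanges::width(gr)
  }
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Extract the subfamily token from RepeatMasker-style ids
#'
#' `"L1PA7:L1:LINE"` (and the simulator's `"L1PA7:L1:LINE:012"`) map to
#' `"L1PA7"`: the first colon-separated token.
#'
#' @param ids character vector of locus ids.
#' @return character vector of subfamily names.
#' @export
subfamilyOf <- function(ids) vapply(strsplit(ids, ":", fixed = TRUE),
                                    `[[`, "", 1L)

#' Read gene models from a GTF file
#'
#' Consumes 1-based inclusive GTF via `rtracklayer`, keeps `exon`
#' features, groups them per `gene_id` (overlapping exon records of one
#' gene are merged), and takes the gene body from a `gene` feature when
#' present, else from the min/max exon span.
#'
#' @param path GTF file path.
#' @return a `GRanges` of gene bodies with `gene_id`, `gene_name`,
#'   `biotype`, `labels` and an `exons` `GRangesList` metadata column.
#' @export
readGtfGenes <- function(path) {
  gtf <- rtracklayer::import(path, format = "gtf")
  ex <- gtf[gtf$type == "exon"]
  if (!length(ex)) stop("no exon features in ", path)
  if (any(is.na(ex$gene_id)))
    stop("exon feature without gene_id attribute in ", path)
  exons <- GenomicRanges::reduce(
    GenomicRanges::split(GenomicRanges::granges(ex), ex$gene_id),
    ignore.strand = TRUE)
  ids <- names(exons)
  bodyFeat <- gtf[gtf$type == "gene"]
  bodies <- unlist(base::range(exons, ignore.strand = TRUE))
  if (length(bodyFeat)) {
    m <- match(ids, bodyFeat$gene_id)
    hit <- !is.na(m)
    if (any(hit)) {
      IRanges::ranges(bodies)[hit] <- IRanges::ranges(bodyFeat)[m[hit]]
    }
  }
  genes <- bodies[ids]
  names(genes) <- ids
  meta <- ex[match(ids, ex$gene_id)]
  S4Vectors::mcols(genes)$gene_id <- ids
  S4Vectors::mcols(genes)$gene_name <-
    if (!is.null(meta$gene_name)) meta$gene_name else ids
  S4Vectors::mcols(genes)$biotype <-
    if (!is.null(meta$biotype)) meta$biotype else
      if (!is.null(meta$gene_biotype)) meta$gene_biotype else NA_character_
  S4Vectors::mcols(genes)$labels <-
    if (!is.null(meta$labels)) meta$labels else ""
  S4Vectors::mcols(genes)$exons <- exons[ids]
  GenomicRanges::sort(genes, ignore.strand = TRUE)
}

#' @rdname readGtfGenes
#' @param genes a gene-model `GRanges` as returned by [readGtfGenes()] or
#'   [simulateAnnotation()].
#' @export
writeGtfGenes <- function(genes, path) {
  mc <- S4Vectors::mcols(genes)
  attrOf <- function(i) {
    a <- sprintf('gene_id "%s"; gene_name "%s"; biotype "%s";',
                 mc$gene_id[i], mc$gene_name[i], mc$biotype[i])
    if (!is.null(mc$labels) && nzchar(mc$labels[i]))
      a <- paste0(a, sprintf(' labels "%s";', mc$labels[i]))
    a
  }
  lines <- character()
  for (i in seq_along(genes)) {
    chrom <- as.character(GenomicRanges::seqnames(genes))[i]
    lines <- c(lines, paste(chrom, "sim", "gene",
                            GenomicRanges::start(genes)[i],
                            GenomicRanges::end(genes)[i],
                            ".", "+", ".", attrOf(i), sep = "\t"))
    ex <- mc$exons[[i]]
    for (j in seq_along(ex))
      lines <- c(lines, paste(chrom, "sim", "exon",
                              GenomicRanges::start(ex)[j],
                              GenomicRanges::end(ex)[j],
                              ".", "+", ".", attrOf(i), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a feature-by-sample count matrix from TSV
#'
#' Expects a header row of sample ids and a first column of feature ids.
#' Raw counts must be non-negative; duplicated feature ids and ragged
#' rows are errors.
#'
#' @param path TSV path.
#' @param raw when `TRUE` (default), values are checked to be
#'   non-negative integers.
#' @return a numeric matrix with feature rownames and sample colnames,
#'   orders preserved.
#' @export
readCountsTsv <- function(path, raw = TRUE) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, fill = FALSE,
                          colClasses = list(character = 1))
  ids <- dt[[1]]
  if (anyDuplicated(ids)) stop("duplicated feature ids in ", path)
  m <- as.matrix(dt[, -1, with = FALSE])
  if (!is.numeric(m)) stop("non-numeric count values in ", path)
  rownames(m) <- ids
  if (raw) {
    if (any(m < 0)) stop("negative raw counts in ", path)
    if (any(m != floor(m))) stop("non-integral raw counts in ", path)
  }
  m
}

#' @rdname readCountsTsv
#' @param mat matrix with feature rownames and sample colnames.
#' @export
writeCountsTsv <- function(mat, path) {
  dt <- data.table::data.table(feature_id = rownames(mat))
  for (j in colnames(mat)) dt[[j]] <- mat[, j]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read / write the sample sheet (sample_id, group, dataset)
#'
#' @param path TSV path with header.
#' @return data.frame with columns `sample_id`, `group`, `dataset`.
#' @export
readSampleSheet <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  need <- c("sample_id", "group")
  if (!all(need %in% colnames(df)))
    stop("sample sheet must have columns sample_id and group")
  if (is.null(df$dataset)) df$dataset <- "default"
  df
}

#' @rdname readSampleSheet
#' @param samples sample-sheet data.frame.
#' @export
writeSampleSheet <- function(samples, path) {
  data.table::fwrite(samples, path, sep = "\t")
  invisible(path)
}

#' Read a BEDPE paired-fragment file
#'
#' Ten tab-separated columns (chrom1, start1, end1, chrom2, start2, end2,
#' name, score, strand1, strand2) with an optional eleventh
#' `proper_pair` flag (1/0). Both mates are 0-based half-open on disk and
#' converted to 1-based inclusive in memory; `score` holds the mapping
#' quality. Without the eleventh column all pairs are taken as proper.
#'
#' @param path BEDPE path.
#' @return a fragment table (see [simulateFragments()] for the layout).
#' @export
readBedpe <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE, fill = FALSE)
  if (!ncol(dt) %in% c(10L, 11L))
    stop("BEDPE must have 10 (+1 proper_pair) columns, found ", ncol(dt))
  bad <- which(dt[[2]] >= dt[[3]] | dt[[5]] >= dt[[6]])
  if (length(bad)) stop("invalid mate interval at line ", bad[1], " of ", path)
  data.frame(read_id = as.character(dt[[7]]),
             chrom1 = as.character(dt[[1]]),
             start1 = dt[[2]] + 1L, end1 = dt[[3]],
             chrom2 = as.character(dt[[4]]),
             start2 = dt[[5]] + 1L, end2 = dt[[6]],
             strand1 = as.character(dt[[9]]), strand2 = as.character(dt[[10]]),
             mapq = as.integer(dt[[8]]),
             proper_pair = if (ncol(dt) == 11L) as.logical(dt[[11]]) else TRUE,
             stringsAsFactors = FALSE)
}

#' @rdname readBedpe
#' @param fragments a fragment table.
#' @export
writeBedpe <- function(fragments, path) {
  dt <- data.table::data.table(
    chrom1 = fragments$chrom1, start1 = fragments$start1 - 1L,
    end1 = fragments$end1,
    chrom2 = fragments$chrom2, start2 = fragments$start2 - 1L,
    end2 = fragments$end2,
    name = fragments$read_id, score = fragments$mapq,
    strand1 = fragments$strand1, strand2 = fragments$strand2,
    proper_pair = as.integer(fragments$proper_pair))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read / write a bedGraph signal track
#'
#' Four tab-separated columns (chrom, start, end, value), 0-based
#' half-open, no header. Runs are sorted on read; overlapping runs are an
#' error.
#'
#' @param path bedGraph path.
#' @return a sorted `GRanges` with a numeric `score` column.
#' @export
readBedgraph <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE, fill = FALSE)
  if (ncol(dt) != 4L) stop("bedGraph must have 4 columns, found ", ncol(dt))
  if (any(dt[[2]] >= dt[[3]])) stop("empty bedGraph run in ", path)
  gr <- GenomicRanges::sort(grFrom(as.character(dt[[1]]), dt[[2]] + 1L, dt[[3]],
                                   score = as.numeric(dt[[4]])))
  if (any(!is.finite(gr$score))) stop("non-finite signal values in ", path)
  cov <- GenomicRanges::reduce(gr)
  if (sum(GenomicRanges::width(cov)) != sum(GenomicRanges::width(gr)))
    stop("overlapping runs in ", path)
  gr
}

#' @rdname readBedgraph
#' @param track a `GRanges` with a `score` column.
#' @export
writeBedgraph <- function(track, path) {
  track <- GenomicRanges::sort(track)
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(track)),
    start = GenomicRanges::start(track) - 1L,
    end = GenomicRanges::end(track),
    value = S4Vectors::mcols(track)$score)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a retained-intron table
#'
#' Tab-separated with header columns `chrom`, `start`, `end`, `name`,
#' `IRratio`, `IntronDepth`, `Warnings`, `overlaps_known_feature`
#' (the per-intron summary an IRFinder-style quantification produces).
#' Intron coordinates are 0-based half-open on disk.
#'
#' @param path TSV path.
#' @return data.frame with one row per intron; coordinates 1-based
#'   inclusive, `IRratio` validated to lie in [0, 1].
#' @export
readIrTable <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  need <- c("chrom", "start", "end", "IRratio", "IntronDepth", "Warnings",
            "overlaps_known_feature")
  if (!all(need %in% colnames(df)))
    stop("retained-intron table must have columns: ",
         paste(need, collapse = ", "))
  if (any(df$IRratio < 0 | df$IRratio > 1))
    stop("IRratio outside [0, 1] in ", path)
  df$start <- df$start + 1L
  df$overlaps_known_feature <- as.logical(df$overlaps_known_feature)
  df
}

#' @rdname readIrTable
#' @param records retained-intron data.frame.
#' @export
writeIrTable <- function(records, path) {
  out <- records
  out$start <- out$start - 1L
  out$overlaps_known_feature <- as.integer(out$overlaps_known_feature)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
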