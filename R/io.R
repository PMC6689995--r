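## Readers and writers for the standard interchange formats. FASTA/FASTQ
## go through Biostrings; GTF through a writer/reader pair kept
## deliberately plain (tab-separated GTF 2.2, 1-based inclusive
## coordinates, fixed attribute order) so identical objects always
## produce byte-identical files.

#' Write a genome to FASTA
#'
#' @param genome named \code{DNAStringSet}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeGenomeFasta <- function(genome, path) {
  writeXStringSet(genome, path)
  invisible(path)
}

#' Write transcript models to GTF
#'
#' One exon row per record, 1-based inclusive coordinates, attributes in
#' fixed order (\code{gene_id}, \code{transcript_id}, \code{exon_number},
#' \code{exon_id}, \code{gene_biotype}).
#'
#' @param models exon-level \code{GRanges}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeModelsGTF <- function(models, path) {
  md <- mcols(models)
  attrs <- sprintf(
    'gene_id "%s"; transcript_id "%s"; exon_number "%d"; exon_id "%s"; gene_biotype "%s";',
    md$gene_id, md$transcript_id, md$exon_number, md$exon_id, md$biotype)
  lines <- paste(as.character(seqnames(models)), "atlasforge", "exon",
                 start(models), end(models), ".",
                 as.character(strand(models)), ".", attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read transcript models from GTF
#'
#' Reads exon rows of a GTF written by [writeModelsGTF()] (or any GTF
#' carrying \code{gene_id}, \code{transcript_id}, \code{exon_number}
#' attributes on its exon features).
#'
#' @param path GTF file.
#' @return exon-level \code{GRanges} with the package's metadata
#'   columns.
#' @export
readModelsGTF <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  f <- f[vapply(f, function(x) length(x) == 9L && x[3] == "exon", logical(1))]
  if (!length(f)) stop("no exon records in ", path)
  getAttr <- function(attr, key) {
    m <- regmatches(attr, regexec(paste0(key, ' "([^"]*)"'), attr))
    vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_,
           character(1))
  }
  attr9 <- vapply(f, `[`, character(1), 9L)
  gr <- GRanges(vapply(f, `[`, character(1), 1L),
                IRanges(as.integer(vapply(f, `[`, character(1), 4L)),
                        as.integer(vapply(f, `[`, character(1), 5L))),
                strand = vapply(f, `[`, character(1), 7L))
  mcols(gr) <- DataFrame(
    transcript_id = getAttr(attr9, "transcript_id"),
    gene_id = getAttr(attr9, "gene_id"),
    exon_number = as.integer(getAttr(attr9, "exon_number")),
    exon_id = getAttr(attr9, "exon_id"),
    biotype = getAttr(attr9, "gene_biotype"))
  gr
}

#' Write read pairs to FASTQ
#'
#' Constant maximum quality ("I") is written for every base; the
#' strandedness convention (mate 1 sense to the transcript) is carried
#' in the read names.
#'
#' @param reads list with \code{r1}, \code{r2} from [simulateReads()].
#' @param prefix output prefix; writes \code{<prefix>_1.fastq} and
#'   \code{<prefix>_2.fastq}.
#' @return invisibly, the two paths.
#' @export
writeReadsFastq <- function(reads, prefix) {
  paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  for (i in 1:2) {
    x <- reads[[c("r1", "r2")[i]]]
    q <- BStringSet(vapply(width(x), function(w)
      paste(rep("I", w), collapse = ""), character(1)))
    writeXStringSet(x, paths[i], format = "fastq", qualities = q)
  }
  invisible(paths)
}

#' Write/read a TPM matrix as TSV
#'
#' Gene rows, sample columns, first column \code{gene_id}.
#'
#' @param mat numeric matrix (or SummarizedExperiment with a \code{TPM}
#'   assay).
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeExpressionTSV <- function(mat, path) {
  if (is(mat, "SummarizedExperiment")) mat <- assay(mat, "TPM")
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeExpressionTSV
#' @export
readExpressionTSV <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Write/read a homology table as TSV
#'
#' Blast outfmt-6 columns plus \code{sgenus}, \code{sdescription} and
#' \code{qlen}.
#'
#' @param alignments homology data.frame.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeHomologyTSV <- function(alignments, path) {
  write.table(alignments, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeHomologyTSV
#' @export
readHomologyTSV <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write sample metadata as TSV
#'
#' @param sampleInfo data.frame (sample, tissue, animal, sex,
#'   library_type).
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeSampleMetadata <- function(sampleInfo, path) {
  write.table(as.data.frame(sampleInfo), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Generate and write a complete synthetic input set
#'
#' One call materializes everything the pipeline consumes: genome FASTA,
#' models GTF, truth TPM matrix, per-sample FASTQ pairs, a homology
#' table with truth labels, and sample metadata.
#'
#' @param design a \linkS4class{SyntheticDesign}.
#' @param outdir output directory (created if needed).
#' @param nPairs read pairs per sample (default 2000).
#' @param readLen read length (default 100).
#' @param errorRate per-base substitution rate (default 0).
#' @return invisibly, a list of the objects written (genome, models,
#'   expression, reads paths, homology).
#' @export
writeSyntheticData <- function(design, outdir, nPairs = 2000L,
                               readLen = 100L, errorRate = 0) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  gm <- generateGenomeAndModels(design)
  se <- simulateExpression(design, gm$models)
  txSeqs <- transcriptSequences(gm$genome, gm$models)
  geneMap <- transcriptGeneMap(gm$models)

  writeGenomeFasta(gm$genome, file.path(outdir, "genome.fa"))
  writeModelsGTF(gm$models, file.path(outdir, "models.gtf"))
  writeExpressionTSV(se, file.path(outdir, "truth_tpm.tsv"))
  writeSampleMetadata(as.data.frame(colData(se)),
                      file.path(outdir, "samples.tsv"))

  fastqs <- character(0)
  for (s in colnames(se)) {
    ab <- transcriptAbundances(assay(se, "TPM")[, s], geneMap)
    rd <- simulateReads(txSeqs, ab, nPairs = nPairs, readLen = readLen,
                        errorRate = errorRate,
                        seed = design@seed + match(s, colnames(se)))
    fastqs <- c(fastqs, writeReadsFastq(rd, file.path(outdir, s)))
  }

  pept <- data.frame(query_id = names(txSeqs),
                     peptide_length = pmax(60L, width(txSeqs) %/% 6L))
  hom <- simulateHomologyTable(pept, scenarios = "all_pass",
                               seed = design@seed)
  writeHomologyTSV(hom$alignments, file.path(outdir, "homology.tsv"))
  write.table(hom$queryLabels, file.path(outdir, "homology_labels.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(genome = gm$genome, models = gm$models, expression = se,
                 fastqs = fastqs, homology = hom))
}
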