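# Fixture builders shared across test files; everything is generated in code.

ANCHOR <- "AGATCGGAAGAGC"  # Illumina-adaptor-like fixed sequence, 13 nt

write_fastq_lines <- function(lines, path = tempfile(fileext = ".fastq")) {
  writeLines(lines, path)
  path
}

fastq_of <- function(ids, seqs, quals = strrep("I", nchar(seqs)),
                     path = tempfile(fileext = ".fastq")) {
  write_fastq(data.frame(id = ids, seq = seqs, qual = quals), path)
  path
}

bed_lines <- function(lines, path = tempfile(fileext = ".bed")) {
  writeLines(lines, path)
  path
}

chrom_sizes_file <- function(sizes, path = tempfile(fileext = ".tsv")) {
  writeLines(sprintf("%s\t%d", names(sizes), sizes), path)
  path
}

# GRanges of reads placed by midpoint; each read is 1 bp wide so the midpoint
# is unambiguous.
reads_at <- function(mids, strands, chrom = "chrT") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(mids, mids), strand = strands)
}

# Direct, window-free frequency count used as the independent oracle for the
# composition path.
oracle_base_freq <- function(strings, position) {
  ch <- substring(strings, position, position)
  ch <- ch[ch != "N"]
  vapply(c("A", "C", "G", "T"), function(b) mean(ch == b), numeric(1))
}
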