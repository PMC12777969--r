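# Fixture builders. Small SAM/VCF inputs are constructed in code; the larger
# simulated runs are built once per session and cached.

.fx <- new.env(parent = emptyenv())

two_contigs <- function() contig_table(c("chr1", "chr2"), c(1e6, 1e6))

# One alignment record as the extraction functions expect it.
make_rec <- function(read_id = "r1", contig = "chr1", ref_start = 1000L,
                     strand = "+", mapq = 60L, cigar = "100M",
                     is_supplementary = FALSE, sa = NA_character_) {
  data.frame(read_id = read_id, contig = contig,
             ref_start = as.integer(ref_start), strand = strand,
             mapq = as.integer(mapq), cigar = cigar,
             is_supplementary = is_supplementary, sa = sa,
             stringsAsFactors = FALSE)
}

# A segment row for split_read_signatures().
make_seg <- function(query_start, query_end, contig, ref_start, ref_end,
                     strand = "+", mapq = 60L) {
  data.frame(query_start = as.integer(query_start),
             query_end = as.integer(query_end), contig = contig,
             ref_start = as.integer(ref_start),
             ref_end = as.integer(ref_end), strand = strand,
             mapq = as.integer(mapq), stringsAsFactors = FALSE)
}

write_sam <- function(lines, path,
                      contigs = contig_table(c("chr1", "chr2"),
                                             c(1e6, 1e6))) {
  header <- c("@HD\tVN:1.6",
              sprintf("@SQ\tSN:%s\tLN:%d", contigs$name,
                      as.integer(contigs$length)))
  writeLines(c(header, lines), path)
  path
}

sam_line <- function(qname, flag, rname, pos1, mapq, cigar, sa = NULL) {
  line <- paste(qname, flag, rname, pos1, mapq, cigar, "*", 0, 0, "*", "*",
                sep = "\t")
  if (!is.null(sa)) line <- paste0(line, "\tSA:Z:", sa)
  line
}

# The default study fixture: 2 x 500 kb contigs, 40 implanted SVs, 20x
# coverage, seed 42, 10 batches; plus its offline callset and truth.
default_fixture <- function() {
  if (is.null(.fx$default)) {
    dir <- file.path(tempdir(), "svstream-fx-default")
    fx <- simulate_run(dir, seed = 42L, write_fasta = FALSE)
    fx$truth <- read_truth_vcf(fx$truth_vcf)
    fx$offline_vcf <- file.path(dir, "offline.vcf")
    fx$offline <- call_offline(fx$batch_paths, fx$contigs,
                               out_vcf = fx$offline_vcf)
    .fx$default <- fx
  }
  .fx$default
}

# The same conditions with all noise removed: homozygous SVs, no jitter, no
# dropout, no background indels.
noise_free_fixture <- function() {
  if (is.null(.fx$noise_free)) {
    dir <- file.path(tempdir(), "svstream-fx-noisefree")
    fx <- simulate_run(dir, seed = 42L, write_fasta = FALSE,
                       spec = sv_spec(het_fraction = 0),
                       p = sim_params(jitter_sd = 0, dropout = 0,
                                      bg_indel_per_kb = 0))
    fx$truth <- read_truth_vcf(fx$truth_vcf)
    .fx$noise_free <- fx
  }
  .fx$noise_free
}

# The uninterrupted streaming run over the default fixture (reference for
# the recovery-equivalence checks).
streamed_default <- function() {
  if (is.null(.fx$streamed)) {
    fx <- default_fixture()
    out <- file.path(tempdir(), "svstream-out-uninterrupted")
    .fx$streamed <- run_engine(fx$batch_dir, out, fx$contigs)
  }
  .fx$streamed
}
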