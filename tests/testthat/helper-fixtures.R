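# shared fixtures, built in code

# 3-generation, 12-member pedigree with 4 founders, hand-written
fixture_ped_lines <- function() {
  c(
    "F1 gf 0 0 1 BD1 22",
    "F1 gm 0 0 2 unaffected .",
    "F1 c1 gf gm 1 BD1 25",
    "F1 s1 0 0 2 unaffected .",
    "F1 c2 gf gm 2 SZMA 30",
    "F1 s2 0 0 1 unaffected .",
    "F1 c3 gf gm 1 unaffected .",
    "F1 g11 c1 s1 1 BD2 19",
    "F1 g12 c1 s1 2 unaffected .",
    "F1 g21 s2 c2 1 BD1 28",
    "F1 g22 s2 c2 2 RUD 33",
    "F1 g23 s2 c2 1 unknown ."
  )
}

fixture_pedigree <- function() {
  path <- withr::local_tempfile(fileext = ".ped",
                                .local_envir = parent.frame())
  writeLines(fixture_ped_lines(), path)
  read_pedigree(path)
}

# minimal site table for gene_drop
fixture_sites <- function(m = 20, af = 0.3, chrom = "chr1", gene = "G1") {
  tibble::tibble(
    variant_id = sprintf("%s:%d:A:G", chrom, seq_len(m) * 1000L),
    chrom = chrom,
    pos = seq_len(m) * 1000L,
    ref = "A", alt = "G",
    gene = gene, consequence = "missense",
    polyphen2 = 0.5, sift = 0.5,
    af = rep_len(af, m), af_evs = rep_len(af, m)
  )
}

# small deterministic call table: one variant, chosen genotypes
fixture_calls <- function(gts, variant_id = "chr1:100:A:G", dp = 112L) {
  tibble::tibble(
    variant_id = variant_id, chrom = "chr1", pos = 100L, ref = "A", alt = "G",
    gene = "G1", consequence = "missense", polyphen2 = 0.9, sift = 0.1,
    af_evs = 0.001,
    subject_id = names(gts),
    gt = unname(gts),
    ad_ref = ifelse(gts == "hom_alt", 0L, dp %/% 2L),
    ad_alt = ifelse(gts == "hom_ref", 0L, dp %/% 2L),
    dp = dp
  )
}
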