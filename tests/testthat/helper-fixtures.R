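# End-to-end fixture: simulate a small two-species study, write every input
# file to `dir`, and return a config list for run_comparison/run_markers.

build_study_fixture <- function(dir, n_pairs = 20, omega = 0.2,
                                n_fast = 0, fast_omega = 3,
                                n_codons = 200, t = 0.4, kappa = 2,
                                decoys = c(nonreciprocal = 1, protein = 2,
                                           name = 2),
                                seed = 1) {
  omegas <- rep(omega, n_pairs)
  if (n_fast > 0) omegas[seq_len(n_fast)] <- fast_omega
  sim <- simulate_ortholog_pairs(n_pairs, omega = omegas, kappa = kappa,
                                 t = t, n_codons = n_codons, seed = seed)
  go <- simulate_go_annotations(max(50, n_pairs * 2), 6, seed = seed + 1)
  # attach GO terms to the A-side transcripts (recycled over the GO fixture)
  idx <- ((seq_len(n_pairs) - 1L) %% nrow(go$annotations)) + 1L
  go_map_a <- stats::setNames(go$annotations$go_terms[idx],
                              sim$truth$ortholog_map$idA)
  tabs <- simulate_hit_tables(sim$truth, sim$fastaA, sim$fastaB,
                              n_decoys = decoys, seed = seed,
                              go_map_a = go_map_a)
  pile_a <- simulate_pileup(400, data.frame(
    pos = c(50, 150, 300), ref = c("A", "C", "G"), alt = c("G", "T", "A"),
    alt_fraction = 0.5), depth = 40, error_rate = 0, seed = seed + 2,
    contig = "ctgA")
  pile_b <- simulate_pileup(400, data.frame(
    pos = c(80, 220), ref = c("T", "A"), alt = c("C", "T"),
    alt_fraction = 0.5), depth = 40, error_rate = 0, seed = seed + 3,
    contig = "ctgB")

  paths <- list(
    fasta_a = file.path(dir, "a.fa"), fasta_b = file.path(dir, "b.fa"),
    hits_ab = file.path(dir, "ab.tsv"), hits_ba = file.path(dir, "ba.tsv"),
    prot_a = file.path(dir, "pa.tsv"), prot_b = file.path(dir, "pb.tsv"),
    annot_a = file.path(dir, "annot_a.tsv"),
    annot_b = file.path(dir, "annot_b.tsv"),
    obo = file.path(dir, "toy.obo"),
    pileup_a = file.path(dir, "pile_a.tsv"),
    pileup_b = file.path(dir, "pile_b.tsv"))
  write_fasta(sim$fastaA, paths$fasta_a)
  write_fasta(sim$fastaB, paths$fasta_b)
  write_hit_table(tabs$hits_ab, paths$hits_ab)
  write_hit_table(tabs$hits_ba, paths$hits_ba)
  write_hit_table(tabs$prot_a, paths$prot_a)
  write_hit_table(tabs$prot_b, paths$prot_b)
  write_tsv(tabs$annot_a, paths$annot_a)
  write_tsv(tabs$annot_b, paths$annot_b)
  writeLines(go$obo, paths$obo)
  write_tsv(pile_a$pileup, paths$pileup_a)
  write_tsv(pile_b$pileup, paths$pileup_b)

  cfg <- c(paths, list(seed = seed, outdir = file.path(dir, "out")))
  list(config = cfg, sim = sim, tabs = tabs, go = go,
       pile_a = pile_a, pile_b = pile_b)
}
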