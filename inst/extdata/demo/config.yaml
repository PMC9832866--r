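species1:
  name: spA
  counts: spA_counts.tsv
  catalog: spA_catalog.tsv
  fasta: spA_genome.fa
  gff: spA_genes.gff3
species2:
  name: spB
  counts: spB_counts.tsv
  catalog: spB_catalog.tsv
  fasta: spB_genome.fa
  gff: spB_genes.gff3
orthologs: orthologs.tsv
motifs: motifs.meme
seeds:
  species1: spA_TF_L1_01
  species2: spB_TF_L1_01
thresholds:
  upstreamLength: 500
  hubCutoff: 6
outdir: demo_out
seed: 1
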