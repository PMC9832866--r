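file	md5
motifs.meme	99b75dbcd997a408f64c7a3dd890eb8d
orthologs.tsv	c69ede1311796e610adf3b0a009ab3d1
spA_catalog.tsv	dee57b1560257796305858e78560485d
spA_counts.tsv	c776130b039c0b890e8df4628f12c18a
spA_genes.gff3	be03d1995394b14c83ebf89321275818
spA_genome.fa	30d61f99a6575595a6908bf699826f13
spA_true_hits.tsv	c1282af495a7ef2a6df094dfbaefc229
spB_catalog.tsv	43f1c9c82a6505f8f75b874a5d879704
spB_counts.tsv	044322d50fd43a692ed52587771459bb
spB_genes.gff3	43ee0eb62d38285ac48c8e145f5f3005
spB_genome.fa	251773ca1e987e05662733c53ca23391
spB_true_hits.tsv	2d797c5264653a4f4214674a059e8aac
truth_edges.tsv	8e349cb71ccf850ebc608cdcacab1c23
truth_enzymes.tsv	ff8e1d2736099bbec7bca4e6e87bfe0b
truth_tf_levels.tsv	084e0469f0104a92fa97a3694cc43449
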