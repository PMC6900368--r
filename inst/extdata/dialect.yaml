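# Dialect of the bundled annotated variant tables: column-name -> field.
build: hg19
missing: ["—", ".", ""]
columns:
  chrom: Chromosome
  pos: Position
  variant_id: ID
  gene: Gene
  exon: Exon
  cdna_change: cDNA
  protein_change: Protein
  consequence: Consequence
  ref_allele: Ref
  alt_allele: Alt
  depth: Depth
  clinvar: Clinvar
af:
  gnomad: GnomAD
  topmed: TOPMED
  exac: ExAC
predictors:
  sift: SIFT
  polyphen2_hdiv: Polyphen2_HDIV
  polyphen2_hvar: Polyphen2_HVAR
  lrt: LRT
  mutation_taster: MutationTaster
  mutation_assessor: MutationAssessor
  provean: PROVEAN
  fathmm: FATHMM
  metasvm_pred: MetaSVM_pred
scores:
  gerp_rs: GERP_RS
  metasvm: MetaSVM_score
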