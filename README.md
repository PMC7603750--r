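# CysConserve

Conserved amino-acid detection across species proteome panels.

Cysteine thiols carry a uniquely rich set of post-translational
modifications (disulfides, sulfenic acids, S-nitrosylation,
S-glutathionylation), and a cysteine that is conserved across a deep
species panel is a strong candidate for such regulation. CysConserve is
for protein biochemists who want an in-silico shortlist of candidate
PTM sites before committing to wet-lab validation: given query proteins
and one proteome FASTA per species, it reports, for every occurrence of
a target amino acid (cysteine by default; any letters, e.g. `CWSTYM`,
can be analysed), how many species retain exactly that residue at the
homologous position and how significant that conservation is.

## Method in brief

Per species, the query is aligned (exact Smith–Waterman, BLOSUM62,
affine gaps 11/1) against every sequence; candidates are filtered by
e-value (Karlin–Altschul, $E = Kmn\,e^{-\lambda S}$), kept only within
a relative raw-score band (≥ 0.8 × the species' best hit) and capped at
9. For each target-residue occurrence the candidates are tried
best-first until one carries the residue opposite the query position —
so a residue lost in one paralog but present in another still counts
for the species. The chosen representatives are aligned by a greedy,
query-anchored progressive global alignment ("once a gap, always a
gap"). With $k$ of $n$ homolog-bearing species showing the identical
letter at the aligned column, the residue's score is $k/n$ and its
p-value is the exact Poisson-binomial upper tail
$P(X \ge k)$, $X = \sum_s \mathrm{Bernoulli}(q_s)$ with
$q_s = 1 - \mathrm{identity}_s$, so conservation is judged against the
whole-protein background. Residues with $p \le 0.01$ are classified
putatively conserved, and every residue gets a neighbour-joining tree
(p-distances) with presence-annotated leaves in Newick format.

## Worked example

```r
library(CysConserve)

# a synthetic 8-species ortholog family with known truth:
# cysteines held at positions 30 and 80, position 80 knocked out in sp05
fam <- generateFamily(familySpec(seed = 42, nSpecies = 8,
  seqLength = 120, divergence = 0.15,
  conservedPositions = c(30, 80), lossMap = list(sp05 = 80L)))

mat  <- substitutionMatrix()          # bundled BLOSUM62
hits <- searchAllSpecies(fam$query, fam$db, mat)
rep  <- analyzeProtein(fam$query, hits, fam$db, mat)
residueResults(rep)
#>   position targetAA k n score       pValue conserved
#> 1       30        C 8 8 1.000 6.315849e-07      TRUE
#> 2       80        C 7 8 0.875 2.668424e-05      TRUE
```

Position 30 is found in all 8 species (score 1.00); position 80 is
found in 7 of 8 (score 0.88 after rounding) because the generator
deleted it in one species; both tails are far below 0.01, so both are
classified putatively conserved. `residueTree(rep@assessments[[2]])`
returns the corresponding tree; its leaf labels end in `|C80+` or
`|C80-` according to presence.

The same analysis runs from the shell over FASTA files:

```sh
cysconserve --query query.fasta --panel panel.tsv \
            --target-aa C --alpha 0.01 --out results_dir
```

(`panel.tsv` holds one `species<TAB>proteome.fasta` line per species;
the script is installed under `exec/` in the package directory.)
Outputs: `results.tsv` (per-residue scores and p-values plus a per-
protein summary row), `alignments.txt` (one alignment block per
residue), `trees/*.nwk` (one Newick tree per residue) and `run.log`.
Identical inputs always produce byte-identical outputs.

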