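---
title: "Detecting conserved amino acids across species panels"
author: "CysConserve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting conserved amino acids across species panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CysConserve)
```

## The problem

Post-translational modifications (PTMs) act on specific amino-acid side
chains — above all on cysteine thiols, whose reversible oxidation states
(disulfides, sulfenic acids, S-glutathionylation, S-nitrosylation)
regulate protein function. A residue whose modification is beneficial
tends to be retained through evolution, so strong conservation of a
cysteine across a deep species panel is evidence that the site is
functionally and perhaps redox-relevant. CysConserve turns this idea
into a pipeline: given a query protein and one proteome per species, it
asks, for every occurrence of a target amino acid in the query, in how
many species the closest homolog retains exactly that residue at the
homologous position, and how surprising that count would be by chance.

## The procedure

For each query protein:

1. **Per-species homolog search.** The query is aligned locally
   (Smith–Waterman, affine gaps, BLOSUM62) against every sequence of
   each species. Raw scores are converted to e-values with the
   Karlin–Altschul closed form $E = K m n e^{-\lambda S}$ using
   published gapped-BLOSUM62 constants ($\lambda = 0.267$,
   $K = 0.041$). Hits above the e-value cutoff are dropped; of the
   survivors only those scoring at least `relScoreCutoff` (default 0.8)
   times the species' best raw score are kept, capped at `maxHits`
   (default 9) candidates. The relative band is read as within-species:
   it prunes clearly inferior paralogs while retaining close ones.

2. **Candidate iteration per residue.** For each occurrence of the
   target amino acid, every species' candidates are tried best-first;
   the first whose global pairwise alignment to the query places the
   target residue opposite the query position becomes that species'
   representative. This guards against gene duplication: a residue lost
   in one paralog but kept in another still counts as conserved in the
   species. If no candidate carries the residue, the best-scoring
   candidate represents the species and the species counts as
   non-conserving. Species without any accepted candidate are excluded
   from the denominator entirely.

3. **Greedy progressive multiple alignment.** The representatives are
   inserted one by one into a query-anchored profile, in descending
   order of similarity to the query, by global profile–sequence
   alignment ("once a gap, always a gap"). Column scores are the mean
   substitution score of the incoming residue against the column's
   residues, with gap rows contributing zero; gap penalties are the
   same as in the search step (open 11, extend 1), and terminal gaps
   are penalized like internal ones — the candidates were pre-filtered
   for high similarity, so true end-to-end global alignment is
   appropriate. With two sequences the procedure is exact (it equals
   the optimal pairwise global alignment); with more it is the standard
   greedy approximation, chosen for determinism and speed.

4. **Score and significance.** With $n$ species represented and $k$ of
   them showing the identical target letter at the query position's
   alignment column, the conservation score is $k/n$ (reported at full
   precision, printed with two decimals, rounded half-up). Presence
   demands the identical letter: conservative substitutions (serine for
   cysteine, say) count as absent, because PTM chemistry is
   letter-specific. Significance uses a Poisson-binomial null: species
   $s$ shows the residue by chance with probability
   $q_s = \mathrm{clamp}(1 - \mathrm{identity}_s,\ 10^{-6},\ 1 - 10^{-6})$,
   where identity is the fraction of query residues identically
   conserved in that species' representative row — so the null folds in
   the whole-protein conservation, and a residue only stands out if it
   is more conserved than its protein background predicts. The p-value
   is the exact upper tail $P(X \ge k)$ of the sum of independent
   Bernoulli$(q_s)$ variables, computed by $O(n^2)$ dynamic-programming
   convolution. A residue is putatively conserved when
   $p \le \alpha$ (default $\alpha = 0.01$, boundary inclusive).

5. **Per-residue trees.** For every analysed residue a
   neighbour-joining tree is built from uncorrected p-distances
   (mismatches over mutually ungapped columns) between the alignment
   rows, with negative branch estimates clamped to zero. Leaves are
   labelled `species|accession|C126+` / `…-` by presence, and trees are
   serialized to Newick.

```{r example}
fam <- generateFamily(familySpec(seed = 42, nSpecies = 8,
  seqLength = 120, divergence = 0.15,
  conservedPositions = c(30, 80), lossMap = list(sp05 = 80L)))
mat <- substitutionMatrix()
hits <- searchAllSpecies(fam$query, fam$db, mat)
report <- analyzeProtein(fam$query, hits, fam$db, mat)
residueResults(report)
```

## Parameters that matter

| parameter        | default | meaning |
|------------------|---------|---------|
| `gapOpen` / `gapExtend` | 11 / 1  | affine gap costs, in substitution-matrix units; a gap of length $L$ costs $\mathrm{open} + (L-1)\,\mathrm{ext}$ |
| `evalueCutoff`   | 1e-5    | maximum e-value for a candidate |
| `maxHits`        | 9       | candidates per species tried during the iteration |
| `relScoreCutoff` | 0.8     | within-species relative score band |
| `lambda`, `K`    | 0.267, 0.041 | gapped-BLOSUM62 Karlin–Altschul statistics |
| `targetAA`       | `"C"`   | residue letter(s) analysed (any of CWSTYM or others) |
| `alpha`          | 0.01    | classification threshold, inclusive |

The e-value cutoff and gap penalties are this package's defaults,
chosen at standard protein-search values; they are exposed so users can
match any external search engine they substitute via the tabular-hit
adapter.

## Design choices where the design was open

- **Built-in exact aligner instead of a heuristic engine.** The
  scientific content is the selection rule (relative band, 9-candidate
  iteration) and the conservation statistic, not the search heuristics,
  so the default engine is exact Smith–Waterman; a 12-column tabular
  adapter accepts output of any standard protein-search tool for large
  databases. This removes binary dependencies and makes runs
  deterministic.
- **The relative band is per species.** The 0.8 cutoff is applied
  within each species' candidate set, relative to its best raw score —
  the reading consistent with its purpose of pruning paralogs during
  the per-species iteration.
- **Significance model.** The Poisson-binomial tail with
  $q_s = 1 - \mathrm{identity}_s$ is this package's concrete
  realization of a significance value combining positional occurrence
  with whole-protein conservation. Its two desirable properties are
  built in: residues of one protein with equal $k$ share identical
  p-values, and the tail is non-increasing in $k$. Other reasonable
  nulls exist (column-frequency based, amino-acid-composition based);
  the classification boundary and the score itself do not depend on
  that choice.
- **Identical-letter presence.** Conservative substitutions are counted
  as absence, because the target chemistry (thiol redox,
  phosphorylation) is tied to the exact side chain.
- **One alignment per residue, cached.** Different residues may pick
  different representatives (the iteration may swap in a
  residue-bearing paralog), so each residue owns its alignment;
  alignments are cached by representative set, so in the common case
  one protein builds one alignment.
- **Two-taxon trees.** A tip-to-tip edge cannot be represented in a
  `phylo` object, so the two-leaf case splits the distance evenly over
  two pendant branches; the leaf-to-leaf path length equals the input
  distance.

## Numerical choices

Scores are exact integer sums in matrix units. The conservation score
is kept at full precision internally (`score * n == k` exactly) and
rounded half-up only when printed, so $16/18$ prints as 0.89 and
$14/18$ as 0.78. Chance probabilities are clamped to
$[10^{-6}, 1-10^{-6}]$ to keep p-values inside $(0, 1]$ even for
identical homologs. Tie-breaks are fixed everywhere: hits sort by raw
score, then e-value, then accession; profile-alignment traceback
prefers match over gap-in-sequence over gap-in-profile; representatives
with equal scores keep species-panel order. Degenerate inputs (a
species with no hits, a query with no target residues, a residue pair
with no mutually ungapped columns) are handled as empty results,
empty reports, and an explicit error, respectively.

## What the synthetic generator emulates — and what it does not

`generateFamily()` builds one ortholog per species by independent
per-site substitution of a random query at a per-species divergence
rate, holding chosen positions fixed at the target residue, knocking
the residue out in chosen species, and optionally adding paralogous
decoys (closer or more distant than the ortholog, with or without the
residue). Because substitutions are i.i.d. and indel-free by default,
the expected $(k, n)$ per position is known exactly, which is what the
recovery tests assert, and stray target residues are scrubbed so the
truth table is exact. The generator deliberately does **not** simulate
tree-structured evolution, rate heterogeneity across sites, domain
architecture, or compositional bias. Passing the recovery tests
therefore shows the machinery is correct under controlled conditions —
it does not certify performance on real proteomes, where paralogy
structure and alignment ambiguity are harsher. Test problem sizes
(panels of 5–21 species, 120–250-residue queries, divergence up to
0.25, 20 seeds per condition) were chosen so the whole suite stays
desk-scale; the stress condition for the candidate iteration uses
decoys derived at zero extra divergence, which outrank the true
orthologs by construction while the orthologs remain inside the 0.8
band.

## Known limitations

- The p-value model is a plausible, internally consistent choice, not a
  reverse-engineered reproduction of any particular published tool's
  unpublished formula; order of magnitude and classification behave
  comparably, digit-level agreement is not claimed.
- No multiple-testing correction is applied across residues or
  proteins.
- The greedy alignment has no refinement pass; for low-similarity
  families a consistency-based or iterative aligner would be more
  accurate (the candidates' high-similarity pre-filter mitigates this).
- p-distances are uncorrected; for deeply diverged panels a
  model-corrected distance would be preferable.
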