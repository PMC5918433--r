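---
title: "Evaluating candidate variants with an explicit generative read model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating candidate variants with an explicit generative read model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varodds)
```

## The problem

Upstream variant callers emit candidate SNPs and indels together with a
quality score, but those scores are tied to a particular alignment of the
reads: multi-mapped reads, ambiguous gap placement around indels, and reads
that really derive from repeat copies absent from the reference all distort
pileup-based evidence. `varodds` re-evaluates each candidate by asking a
more direct question: *is the read data more probable if the sample genome
carries this variant than if it matches the reference?* The answer is
reported as a marginal posterior odds ratio, suitable for ranking a callset
or prioritising validation experiments, particularly in the single-sample
setting where population panels and training data are unavailable.

## The model

For a candidate variant the package builds explicit hypotheses about the
sample genome: the reference hypothesis, and hypotheses in which the
variant (homozygously or heterozygously) is applied to the reference. A
hypothesis genome $G$ is treated as a diploid multiset of read-length
substrings ("segments"), and the probability of one read $r$ of length
$\ell$ is a sum over segments:

$$
P[r \mid G] \;\propto\; \sum_{g \in G} \prod_{i=1}^{\ell} P[g_i \mid r_i],
\qquad
P[g_i \mid r_i] = \begin{cases} 1 - e_i & r_i = g_i \\ e_i/3 & \text{otherwise}
\end{cases}
$$

where $e_i$ is the base-call error probability from the Phred quality.
Summing over every segment overlapping the read's mapped location absorbs
local gap-placement ambiguity — no single alignment of the read to the
hypothesis is privileged. Two standard approximations make this tractable:
reads that do not overlap the candidate's neighborhood are ignored (they
cancel in every ratio), and only segments overlapping the locations a read
maps to are summed. For a heterozygous hypothesis, the per-read likelihood
is the average of its two chromosome-copy windows, so that heterozygous
and homozygous hypotheses are on the same scale. The model assumes no
insertion/deletion sequencing errors within a read; indel *variants* are
handled exactly (they are part of the hypothesis window), but indel
*errors* are not, which is the main model limitation for long-homopolymer
data.

### Mini-haplotype clusters

Nearby candidates interact: a read spanning two close variants is evidence
about both jointly. Candidates whose reference footprints lie within 10 bp
(default `max_dist`) are chained into a cluster, and every subset of the
cluster is considered as a joint hypothesis, heterozygous or homozygous
(mixed zygosity is not considered), up to 1024 subset combinations
(default `max_combos`). Priors play the role of a multiplicity correction:
the reference hypothesis always receives 0.5, and the remaining 0.5 is
split evenly over all alternative hypotheses of the cluster. The score of
one variant $v$ marginalises over the cluster:

$$
\frac{P[R \mid v]}{P[R \mid \text{not } v]}
 = \frac{\sum_{G \in \mathbf{G}_v} P[G]\, P[R \mid G]}
        {\sum_{G \in \mathbf{G}_u} P[G]\, P[R \mid G]}
$$

with $\mathbf{G}_v$ the hypotheses containing $v$ and $\mathbf{G}_u$ those
not containing it (possibly containing its neighbours). When $2^k$ exceeds
the cap, subsets are admitted in a fixed order — empty set, singletons,
the full set, then by increasing size — so every variant is always
evaluated at least as a singleton.

### Paralogs inside and outside the reference

A read mapping to several reference locations contributes the segment sums
of *all* its locations to every hypothesis; since that mass is identical
across hypotheses, spurious ratios from multi-mapped reads are damped
toward 1. Reads from repeat copies that exist in the sample but not in the
reference ("reference-external" reads) cannot be explained this way, so
each read also receives an outside-source term

$$
m_r \, h \sum_{f:\ \mathrm{HD}(f, r^*) \le 1} \prod_i P[f_i \mid r_i]
$$

— the total probability of all sequences within Hamming distance one of
the called read $r^*$, scaled by the constant $h$ (default $10^{-4}$) and
by the read's mapping multiplicity $m_r$ (segments with many paralogs
inside the genome are the ones likely to have more outside it). The
neighborhood sum has the closed form
$\prod_i(1-e_i)\bigl(1 + \sum_i \frac{e_i}{1-e_i}\bigr)$, so no
enumeration is performed. The effect is that a read fitting *every*
hypothesis poorly — more mismatches than its qualities explain — is mostly
absorbed by the outside term and contributes little to the odds, instead
of randomly inflating whichever hypothesis it happens to fit less badly.
Setting `h = 0` disables the term.

## Numerical choices

All probability arithmetic is carried out in natural-log space with
log-sum-exp; a product over a 100-base read underflows double precision by
hundreds of orders of magnitude. Error probabilities are clamped to
$[10^{-6}, 0.75]$ after Phred conversion: $e_i \in \{0, 1\}$ breaks both
branches of the base model and 0.75 is the uniform-base limit. `N` bases
(in read or segment) score $1/4$ regardless of quality. Reads without
quality strings are assigned Q20 with a warning. Reads are summed in a
fixed order (read id, then hypothesis index), so identical inputs give
bit-identical output. Ties between hypotheses in the best-hypothesis
report are broken toward fewer variants.

Haplotype windows extend $\ell + \mathrm{pad}$ (pad default 2 bp) beyond
the cluster's reference footprint on each side, which guarantees every
read overlapping the cluster finds all of its shifted segments inside the
window. Reference and alternative windows of an indel hypothesis differ in
length, so their segment counts differ slightly; following the
proportionality above, no per-segment-count normalisation is applied.
Soft-clipped bases are trimmed before scoring (they have no reference
counterpart under the ungapped segment comparison), and aligner-reported
indels inside a read are deliberately ignored — only the called sequence,
its qualities and the leftmost mapped position are used, because the
segment sum re-scores the read against each explicit window.

## What the simulator emulates — and what it does not

`simulate_dataset()` generates the package's entire test bed: a random
reference contig (default 100 kb), planted SNPs and geometric-length
indels (p = 0.5, capped at 10 bp) with a configurable heterozygous
fraction applied to two haplotype sequences, paired-end 100 bp reads with
insert size 500 ± 30 bp at 30× (or any) coverage, uniform Q20 base errors,
and decoy candidates — false VCF entries at least $2\ell$ away from any
true variant — standing in for an upstream caller's false positives. A
separate mode copies a reference region, mutates it at 3% divergence and
emits reads from the copy at the original coordinates, emulating an
off-reference repeat copy for exercising the outside-paralog term.

Reads are emitted at their *true* source positions (projected from
haplotype to reference coordinates) with all-`M` CIGARs: mapping is out of
scope, and this isolates the scorer from mapper behaviour. Consequently
the simulation does not probe mapper-induced mis-placement, quality
miscalibration, per-cycle error profiles, indel sequencing errors, or real
variant-density patterns; passing tests demonstrate the probabilistic
machinery and its discrimination under idealised placement, not
performance on real libraries. Default problem sizes (100 kb, 50 planted
variants + 50 decoys, 10 simulation seeds for ranking summaries) were
chosen as the smallest sizes at which the ranking statistics are stable;
they are configuration, not claims of equivalence with any real dataset.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_dataset(sim_config(seed = 1), outdir = tempfile())
vs <- score_variants(sim$paths[["reference"]],
                     sim$paths[["candidates"]],
                     sim$paths[["alignments"]])
summary(vs)
rk <- rank_variants(vs)
precision_recall(rk, sim$labels)
```

`score_variants()` returns a `variant_scores` data frame: one row per
candidate with its natural-log marginal odds (`log_odds`), the posterior
probability `odds/(1+odds)`, the number of reads used, the hypothesis
count of its cluster, and flags (`no_data` for uncovered clusters, which
are reported at log-odds 0 rather than dropped; `high_depth` when the
10,000-read cluster cap was hit — extreme depth usually signals
copy-number artefacts rather than evidence). Ranking uses the log-odds
(the posterior is monotone in it, so the two orderings coincide), with
positional tie-breaks for determinism; `precision_recall()` reports
precision in increments of 50 calls, counting a call correct when it
matches a truth variant in sequence and position, regardless of zygosity.

## Design decisions that were genuinely open

* **Heterozygous likelihood scale.** Averaging the two copy windows (rather
  than summing them unnormalised) keeps het and hom hypotheses comparable;
  with unnormalised sums a het hypothesis would receive roughly twice the
  segment mass of either homozygous alternative purely from its larger
  multiset.
* **Combination-cap order.** Beyond 10 clustered variants the subset cap
  admits the empty set, singletons, the full set, then subsets by size;
  singletons first guarantees every variant is scored.
* **Overlapping alleles.** Two candidates touching the same reference base
  (e.g. a split multi-allelic site) cannot coexist on one haplotype; such
  subsets are skipped with a warning while the singletons remain.
* **Paired ends.** Mates are scored as independent reads; insert-size
  information is unused by the per-read model.
* **Mapping-quality filter.** None by default — the outside-paralog term
  is the model's mechanism for doubtful mappings; a `min_mapq` option
  exists for pipelines that insist.
* **Empty-set accounting.** The 1024-combination cap counts the empty
  (reference) subset, so ten variants expand to exactly $2^{10} = 1024$
  combinations and $1 + 2(2^{10}-1)$ hypotheses.

## Known limitations

Indel sequencing errors are not modelled inside $P[r \mid g]$; candidate
lists are assumed normalized (left-aligned, decomposed) — a shared-suffix
warning is emitted but no normalisation is attempted; zygosity is reported
only as the best-hypothesis descriptor, not called; clusters are evaluated
independently (no phasing across clusters); and copy-number variation is
outside the model — very deep pileups are capped and flagged instead.
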