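---
title: "Inferring Atomic Regulons and reconciling them with a regulatory network"
author: "AtomicRegulons package authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring Atomic Regulons and reconciling them with a regulatory network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AtomicRegulons)
```

# The model

An **Atomic Regulon (AR)** is a set of genes with identical binary ON/OFF
expression profiles across every sample of an expression compendium: in any
one sample the members are either all ON or all OFF. ARs sit below the two
classical co-regulation abstractions — the *regulon* (genes controlled by one
regulator) and the *stimulon* (genes responding to one stimulus) — and form
the finest co-regulation unit that expression data alone can support. A gene's
**stimulus signature**, its set of (stimulus, induced/repressed) pairs in a
curated regulatory network, predicts its AR: genes taking part in identical
sets of stimulons with identical induction/suppression profiles should land in
the same AR. The package exploits this equivalence in both directions:
expression-derived ARs are confronted with a stimulus-annotated network to
validate it, flag inconsistencies, and propose missing regulatory links.

The pipeline has four stages:

1. **Binarization** (`binarizeExpression`): each gene's normalized log2
   expression is reduced to per-sample ON / OFF / UNCERTAIN calls.
2. **Draft regulons** (`predictOperons`, `buildDraftRegulons`): crude operon
   predictions (same-strand adjacency within an intergenic gap) are joined
   through shared subsystem membership into hypotheses of co-regulation.
3. **AR inference** (`inferAtomicRegulons`): drafts are decomposed into
   groups with identical call profiles and expanded across drafts, gated by
   each member's average Pearson correlation (PCC) to its co-members.
4. **Reconciliation** (`classifyConsistency`, `stripRegulators`,
   `propagateStimuli`, `enrichMetadata`, `essentialCheck`): ARs are
   classified against the network into four categories — *consistent*,
   *consistent with missing stimuli*, *inconsistent*, *empty* — and curated.

# Binarization

For each gene the values are split into two clusters by the exhaustive
variance-minimizing cut of the sorted values (all *n − 1* cuts are scored;
no random initialization, so results are reproducible). The gene is bimodal
when the two cluster means differ by at least `minSeparation` (default 1.0
log2 units); calls are then decided by the side of the boundary midpoint,
with a guard band of `uncertainBand` around the midpoint left UNCERTAIN.

Two numerical choices deserve comment.

**The discontinuity rescue.** The variance-minimizing cut has a blind spot:
when a gene is ON in only a handful of samples, bisecting the majority mode
costs less variance than separating the true minority cluster, and the gene
would collapse to unimodal. Genes ON in a few samples are precisely the
interesting ones (prophage genes induced only under DNA damage, sporulation
genes ON only late in a time course), so when the optimal cut is unseparated
the gene is re-examined at the largest discontinuity of its sorted values: if
that single gap reaches `minSeparation/2` *and* the resulting cluster means
still differ by `minSeparation`, the gene is split there. A unimodal
Gaussian gene essentially never shows a consecutive-value gap of that size
(it would require a ≈2.2-sigma spacing at the default noise), so the
unimodal gate is preserved.

**The guard band.** `uncertainBand` defaults to half of `minSeparation`. The
band must cover the region where the two modes' noise distributions overlap;
a band much narrower than the noise scale leaves occasional wrongly-decided
calls, and a single wrong decided call is enough to expel a gene from its AR
(profile identity tolerates UNCERTAIN but never a decided conflict). Setting
`uncertainBand = 0` recovers a strictly binary model.

Unimodal genes are constitutive: all-ON when the gene's median sits at or
above the `globalOnQuantile` (default 0.40) quantile of the whole matrix,
all-OFF otherwise. All three parameters are this package's own defaults —
the binarization behind published full-compendium AR sets is not public —
and are surfaced in the API and the run configuration.

# Draft regulons

Operon prediction is deliberately crude: maximal runs of same-contig,
same-strand genes with intergenic gaps of at most `maxGap` (default 150 bp;
negative gaps from overlapping genes count as small). No promoter or
terminator evidence is used, and the first and last operon of a circular
chromosome are never joined — at one junction in thousands of operons the
effect is negligible against the simpler contract. Subsystems (curated sets
of functionally related genes) then act as glue: operons contributing genes
to a common subsystem join one draft regulon (union–find over the bipartite
operon–subsystem graph). Drafts only merge operons, never split them.

# AR inference

Profile identity (`profilesIdentical`) requires zero decided conflicts and at
least `minCodecided` (default 10) co-decided samples — without the latter,
two mostly-UNCERTAIN genes would count as identical on no evidence.

Inference is greedy and deterministic throughout, trading optimality for
reproducibility: within each draft, genes are grouped in genome order
(decompose); whole groups then merge across drafts in ascending first-locus
order when their consensus profiles are identical *and* every member's
post-merge average PCC stays at or above `minAvgPcc` (default 0.6, on the
continuous expression over all samples). The PCC gate applies to merges
only: published AR tables report within-operon members with average PCC as
low as 0.605, so gating the within-draft decomposition would break up
genuine operons. The gate also keeps constitutively-ON genes from collapsing
into one genome-wide AR: their calls are identical, but their residual
expression is uncorrelated noise, so cross-draft merges fail the gate while
within-operon grouping survives. Groups smaller than `minSize` (default 2)
are reported as *unplaced*, never silently dropped — in the sucrose worked
example, yveA's extra uncharacterized effector leaves it alone with a unique
profile, and its unplaced status is itself informative.

# Reconciliation

`theoreticalARs` partitions genes by exact signature equality; genes with no
stimulus links carry no information and are reported separately rather than
pooled into a fictitious "no-stimulus AR". For consistency classification,
signature comparison ignores sign whenever either link's sign is unknown
(most curated links omit it), but two known, opposite signs conflict. Since
this wildcard equality is not transitive, an AR is *consistent* only when
all pairs of non-empty member signatures agree.

The four categories are mutually exclusive and exhaustive: *empty* (no
member annotated), *consistent* (all annotated, all agreeing),
*consistent with missing stimuli* (agreeing, but some members unannotated),
*inconsistent* (two members disagree). Curation operators mirror the manual
workflow: `stripRegulators` removes genes that encode network regulators
(regulators are routinely captured with their targets, which is undesirable
for regulons used in a network model), and `dropDiscordantMembers` removes
the minority-signature members of inconsistent ARs — both log every removal
and flag, rather than delete, ARs that fall under the size minimum.
`propagateStimuli` turns a consistent-missing AR into concrete proposals:
the consensus signature (and the consensus regulator, when unique) is copied
to each unannotated member, as proposals only.

`enrichMetadata` recovers candidate stimuli from free-text sample metadata:
study ids and description words (minus stop-words, plus word bigrams) become
terms, each scored by the one-sided hypergeometric tail probability of its
overlap with the AR's ON samples, with Benjamini–Hochberg q-values across
terms (candidate shortlist at q ≤ 0.05, a conventional threshold). Ties are
broken in favour of study-id terms — the most specific annotation — then by
larger overlap, then alphabetically. Enrichment looks at ON samples, so a
stimulus that *represses* its AR (the AR is ON by default and switches OFF
under the stimulus) is not recoverable this way; its signal sits in the OFF
samples.

`essentialCheck` is a sanity check on the whole pipeline: a gene essential
for growth cannot be OFF in every condition, so the intersection of the
always-OFF set with an essential-gene list should be empty.

# The synthetic benchmark

`simulateCompendium` generates every input the pipeline reads, plus the
ground truth, reproducibly from one seed. The default configuration is the
package's validation benchmark: 4000 genes laid out in operons (planted-AR
and constitutive operons of 2–4 genes, background operons of 1–4; 80 bp
intra-operon gaps, 500 bp between operons), 50 planted ARs each spanning 1–3
operons tied by a subsystem and wired to 1–3 stimuli, 17% always-ON and 4%
always-OFF genes, and 120 samples in 24 studies. Expression is a two-level
Gaussian model — `off + (on − off) · state + N(0, noiseSd)` with ON at 9 and
OFF at 6 log2 units and noise at 15% of the separation — because the
analysis consumes only the binary abstraction; no mechanistic kinetics, array
artifacts or batch effects are simulated.

Condition design choices, fixed before any benchmarking: each stimulus
belongs to one home study and is applied in at least 3 replicate samples of
it (conditions are assayed in replicate) with at least one control sample;
two stimuli tested in the same study never share an activation pattern,
since identically-applied effectors are definitionally indistinguishable
from metadata; sample descriptions name the stimuli active in that sample,
mimicking curated GEO study explanations; 5% of planted ARs are wired as
repressed (curated stimulon annotations are overwhelmingly inductions).
AR stimulus signatures are unique by construction, so the theoretical ARs of
the true network equal the planted partition exactly.

What passing the benchmark does and does not show: recovery (adjusted Rand
index of inferred vs. planted ARs over planted genes, with unplaced genes as
singletons; ARI = 1 in the noiseless limit, ≥ 0.9 at default noise) is
measured under clean two-level expression with independent Gaussian noise.
Real compendia have probe effects, correlated noise, and intermediate
expression states, so benchmark performance is an upper bound, not a promise.
Network-consistency recovery is reported over ARs containing at least one
network-annotated gene: constitutive ARs have no links at all, and their
*empty* category carries no information about the network's correctness.
Stimulus-recovery is counted as the top enrichment term naming a true
stimulus or its home study — recovering the study is how such inference is
used in practice, with the specific effector identified by reading the study
design.

Benchmark problem sizes used in the shipped tests (4000 genes × 120 samples
for recovery; 300-gene configurations for unit-level properties; a 400-gene
× 269-sample compendium-shaped import smoke test) keep the whole suite
around a minute while exercising every code path at realistic shape.

# Degenerate inputs and tie-breaks

Constant genes are unimodal by construction (never an error); a gene median
exactly at the global quantile threshold counts as ON (so a constant matrix
is all-ON). Ties among equal-variance cuts go to the smallest cut index;
ties in enrichment ranking are resolved as described above; AR ids are
assigned in genome order of each AR's first member. All writers sort rows
(AR id, then locus tag), so identical configuration and seed give
byte-identical outputs.

# Known limitations

* The binarization reconstructs an unpublished procedure; full-compendium AR
  censuses from the original analysis are not expected to reproduce.
* The detection limit for rarely-ON genes at default noise is about 3 ON
  samples; below that, calls collapse to all-OFF.
* Stage-2 merging is greedy; a different merge order could yield a different
  (equally valid) partition in rare ambiguous configurations.
* Repressed stimuli are invisible to ON-sample metadata enrichment.
* Operon prediction ignores circular wrap-around and all evidence beyond
  same-strand adjacency.
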