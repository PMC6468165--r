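---
title: "Quantifying editing progression in U-indel edited mRNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying editing progression in U-indel edited mRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uindel)
```

## The biological problem

Mitochondrial mRNAs of kinetoplastid parasites are made translatable by
uridine insertion/deletion (U-indel) editing: small guide RNAs (gRNAs)
direct the insertion and deletion of uridines at defined positions,
proceeding 3'→5' along the transcript. Amplicon deep sequencing of a
transcript's editing domain captures a population of molecules frozen at
every stage of this progression. `uindel` turns such read populations into
quantitative statements about *where* editing pauses, *what* the
partially edited intermediates look like, and *which* guides could have
produced them.

## The coordinate system

Because editing only ever changes the number of uridines between other
bases, the natural coordinates are **editing sites (ESs)**: every gap
between two consecutive non-T bases of the domain (cDNA sense), numbered
1, 2, … from 3' to 5', following the direction of editing. A transcript's
state is then a vector of U counts, one per site, and the pre-edited and
fully edited templates are just two reference vectors over a shared non-T
**skeleton**. `build_site_table()` compiles a `gene_template()` into this
representation and refuses templates whose skeletons disagree.

Two conventions deserve a note:

* **Boundary sites.** The gaps between the domain's terminal skeleton
  bases and the adjacent never-edited flanks are real editing sites
  (insertions can abut the anchor region), so the flanks are required to
  meet the domain with a non-T base, making those gaps well defined. A
  domain with *k* skeleton bases therefore has *k* + 1 sites.
* **Published labels.** Papers label sites "ES441"-style with numbering
  specific to each gene's full transcript. The mapping from local site 1
  (the 3'-most) to a published label is a pure offset (`es_offset`),
  supplied in the template configuration. A stop site of 0 ("no canonical
  progress") is reported as the label of the site 3' of the domain.

## Classification and landmarks

Reads are collapsed to unique sequences (`collapse_reads()`), anchored by
exact match of both never-edited flanks in either orientation, and the
domain between the flanks is scanned. A read whose domain skeleton
differs from the template's carries a non-T mismatch and is excluded as a
*non-standard* alignment; flank mismatches leave a read *unanchored*.
Both exclusions are deliberate strictness: the flanks are primer-defined
and never edited, so any disagreement there or in the skeleton is
evidence of sequencing error or off-target amplification rather than
editing. Quality strings are ignored; analysis operates on merged
sequence identity.

Each standard read is classified by exact U-count equality with the two
templates (`pre_edited` / `fully_edited`, anything else
`partially_edited`) and landmarked:

* **ESS** — editing stop site: the 5'-most site up to which the read
  matches the fully edited template, all 3' sites matching as well;
* **JSS** = ESS + 1, the junction start site;
* **JES** — the 5'-most site with any editing action (difference from
  the pre-edited template);
* **JL** = max(0, JES − ESS), the junction length in sites.

A pause followed by purely pre-edited sequence has JL 0; a fully
pre-edited read is classified pre-edited, not as a pause at site 0. When
a template requires no editing at all, pre-edited classification wins by
convention.

## Normalization and pause statistics

Standard alignments of each sample are rescaled to a common total
(100 000 by default) so abundances compare across samples; normalized
counts stay fractional — rounding would inject bias no downstream method
asks for. The **stop-site histogram** is the total normalized count of
partially edited sequences at each ESS, over the full site domain with
zeros filled in: the exclusion of pre-edited and fully edited reads
governs which *reads* are counted, not which *sites* appear, and the
outlier statistic below needs the whole distribution.

**Intrinsic pause sites (IPSs)** are histogram outliers per replicate:

> threshold = Q3 + 1.5 · IQR

with quartiles computed by linear interpolation of order statistics (R's
default quantile type 7). The source describing this statistic does not
fix a quartile convention, and membership of borderline sites can depend
on it, so the convention is recorded in the IPS output header. Sites
above threshold in at least `min_support` of *n* replicates (default 4
of 5) are consensus calls, with support *n* distinguished from *n* − 1,
and the degree of pausing reported as the mean of H/threshold across
replicates (per-replicate thresholds; a pooled-threshold variant would
change the number but not the ranking in our simulations).

**Exacerbated pause sites (EPSs)** compare induced (knockdown) and
uninduced groups. Populations are first renormalized after removing
pre-edited sequences — "entered the editing pathway" is operationalized
as *not pre-edited*, so fully edited reads stay in the pool (a flag
removes them too, for designs where that is preferred). Per site, a
two-sample Student's t-test (equal variance, as named; Welch by flag) is
BH-adjusted across all sites of the transcript, and a site is called
when p < 0.05, q < 0.05, the induced mean exceeds the uninduced mean,
and **every** induced replicate exceeds the uninduced mean. With only
two induced replicates, "significantly increased in both replicates" is
ambiguous between this reading and testing each replicate separately;
both are implemented (`rule = "group_t"` vs `"per_replicate"`), the
group test being the default because it uses all data symmetrically.
Zero-variance sites get p = 1 when the means are equal, otherwise a
machine-epsilon variance floor — significance is never invented from
degenerate data. Calls averaging under 500 renormalized counts in both
groups are annotated as low-abundance rather than suppressed.

## Junctions and guide matching

`top_junctions()` groups partially edited reads at a stop site by exact
U-count-vector identity and averages normalized counts across
replicates, **zero-filling** replicates lacking a sequence — an average
over *n* replicates is only well defined that way. The share of the stop
site can be computed against all reads at that ESS or only those that
entered the pathway, because both denominators are in common use.
Junction lengths are binned (0, 1–2, 11–13 by default) and averaged
within sample groups.

Guide matching models the antiparallel mRNA:gRNA duplex with
Watson–Crick and G:U wobble pairs. `predict_templated_block()` walks the
mRNA 3'→5' from an anchor: guide bases that pair the pending skeleton
base close a site; maximal runs of unconsumed purines template that many
uridines at the intervening site. A guide G is consumed by a skeleton C
when it arrives in register and otherwise joins the purine run — the
greedy rule is deterministic and reproduces canonical blocks. Encoded
uridines that the guide does not re-template are deletions (permitted by
default, flagged off for insertion-only analyses). The only gapped
variant supported is the single-base bulge used for misalignment
analysis: bulging one pairing guide U out of register merges its
flanking purine runs — converting, in the canonical construction, a 5-U
site into a 9-U insertion — after which the walk is truncated, since the
shifted register cannot continue pairing. `search_grna_db()` enumerates
anchor placements jointly with anchor length (a cognate guide pairs the
very junction it explains, so maximal-duplex anchoring would swallow the
guiding region), predicts each candidate block and ranks guides by
junction sites exactly explained, then anchor score. Guides annotated to
other transcripts are reported like any other: promiscuous guide usage
is a real phenomenon.

## The synthetic data generator

Deposited sequencing data cannot ship with a package, so validation
rests on a generator that emulates the statistical structure of such
experiments with known ground truth: a class mixture (pre / partial /
full), a categorical stop-site distribution with optional spikes, four
junction mechanisms (no junction; random per-site U jitter with a
junction-length distribution; a pinned merged-run misalignment block; a
pinned alternative-guide block), and a per-base substitution error rate
applied to non-T bases — which guarantees every simulated error is
detectable as a non-standard or unanchored alignment, so the exclusion
filter can be tested independently of the junction analytics.

Default study conditions, chosen once as representative of a wild-type
minimally edited mRNA experiment: 100 000 reads per replicate, 5
replicates, 30% pre-edited / 60% partially edited / 10% fully edited,
stop sites uniform over the sites at which a pause is representable
(those whose next site requires editing), a junction mix of 45% bare
pauses, 35% jitter and 10% each templated mechanism, and a 0.1%
substitution rate. The bundled `demo_template()` is a fixed synthetic
40-site gene (32 sites requiring editing, insertions up to six Us and
deletions) — it resembles no real gene and is labelled synthetic
wherever it appears.

The draw order is part of the contract — class, then stop site, then
mechanism, then junction content, then errors, with replicate *r* seeded
at `seed + r − 1` — so determinism and the sampling scheme itself are
testable. Two constructions keep truth and landmarks consistent by
design: stop-site weights are only accepted at sites whose next site
requires editing (a pause elsewhere is not representable as an ESS), and
a junction-free pause 3' of the first editable site would be
indistinguishable from a pre-edited read, so such draws fall back to the
jitter mechanism.

What the generator does *not* emulate: PCR chimeras and amplification
bias, quality-score structure, indel sequencing errors inside T runs,
and correlated (haplotype-like) junction families beyond the two pinned
mechanisms. Passing tests therefore demonstrate correctness of the
coordinate system, statistics and search — not robustness to artifacts
a real library may contain.

## Numerical and scale choices

Simulation-based checks in the test suite and acceptance script run at
the study scale of 10^5 reads per replicate; consensus and differential
checks use 5 uninduced replicates and the 2-vs-8 knockdown design.
Replicate counts for null calibration (200 null comparisons) were sized
to estimate a ≤10% family-wise null rate with usefully small Monte-Carlo
error while keeping a default test run in the minutes range. Pause-site simulation
studies build populations at the landmark collapse level
(`truth_population(..., collapse = "landmark")`); the test suite asserts
this is exactly equivalent to sequence-level processing for every
statistic downstream of alignment.

## Known limitations

* Exact flank anchoring discards reads with any flank variation; with
  long flanks and high error rates this censors the deepest-error reads
  rather than modeling them.
* Exact-identity junction grouping treats one U of difference as a new
  junction family; `pattern_spec()` offers predicate-based grouping but
  no clustering.
* The duplex model is combinatorial, not thermodynamic: no ΔG, no
  multi-base bulges or internal loops.
* Published ES label offsets are configuration, not inference: they are
  recoverable only from the original template annotations.
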