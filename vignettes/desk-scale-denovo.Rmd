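---
title: "De novo peptide sequencing at desk scale: models, constraints and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{De novo peptide sequencing at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tandemnovo)
```

## The problem

A tandem mass spectrometer isolates a peptide ion (the *precursor*,
with measured m/z and charge), fragments it, and records a peak list
$S = \{(m_i, I_i)\}$ of fragment m/z values and intensities. De novo
sequencing infers the peptide's residue sequence directly from $S$,
without a sequence database: prefix fragments (b ions, and a/c under
other fragmentation chemistries) and suffix fragments (y, z) form mass
ladders whose successive differences are residue masses. Real spectra
make this hard: most spectra are missing at least one fragment ion,
the large majority of peaks are noise, and several residue pairs are
near-isobaric (I/L exactly; Q/K within 0.036 Da).

`tandemnovo` implements the full pipeline at desk scale: a
transformer translates peak lists into peptide tokens; beam search is
constrained so that emitted peptides always match the precursor mass;
a peptide language model filters and re-ranks hypotheses; predicted
peptides are assembled into contigs and mapped onto proteins. A
synthetic-data generator supplies annotated spectra so that every
stage can be trained and tested offline, which also bounds what the
tests demonstrate (see *What the synthetic data does and does not
show*).

## Mass bookkeeping

All masses are monoisotopic: the downstream matching tolerances (0.1
Da per residue, 0.5 Da per prefix) are meaningful only under
monoisotopic bookkeeping. The vocabulary maps residue tokens to
residue masses (20 canonical residues; modified residues are separate
single-character tokens, e.g. phospho-serine `s` = serine + 79.96633
Da) and carries four massless special tokens (pad, start, end, mask).
Fragment conventions are standard: $b_k$ = prefix residues + proton,
$a = b - \mathrm{CO}$, $c = b + \mathrm{NH_3}$, $y_k$ = suffix
residues + water + proton, $z = y - \mathrm{NH_3}$, by default the
radical z-dot ($z + \mathrm{H}$) observed under ETD; plain z is a
constructor switch. The complementarity identity $b_k + y_{n-k} =
M + 2\,\mathrm{proton}$ is property-tested across the vocabulary.

## Spectrum encoding

Each peak's m/z is mapped to a d-dimensional vector with equal
numbers of sine and cosine components; intensity (max-normalised per
spectrum, since absolute scales are instrument-dependent) passes
through a learned affine map; the two are summed. Two frequency
layouts are provided:

* **literal** — the printed formula this implementation follows as
  the `encode_mz()` default: component $i$ is
  $\sin\!\big(m / (\tfrac{\lambda_{max}}{\lambda_{min}}
  (\tfrac{\lambda_{max}}{2\pi})^{2i/d})\big)$ for $i \le d/2$, cosine
  analogue above, with $\lambda_{max} = 10^4$, $\lambda_{min} =
  10^{-3}$. Note the prefactor $\lambda_{max}/\lambda_{min} = 10^7$
  sits inside the wavelength, so effective wavelengths span
  $10^7$–$1.6\times10^{10}$ m/z — far above any spectral m/z, making
  all components nearly constant. It is kept verbatim because it is
  the stated form, and `encode_mz()` is tested against an independent
  transcription of it.
* **paired** — the standard transformer layout that actually spans
  wavelengths $\lambda_{min}$ to $\lambda_{max}$: $d/2$ geometric
  scales $s_k$, components $\sin(m/s_k), \cos(m/s_k)$ interleaved by
  scale. Trained models default to this layout; the literal one is
  untrainable for the reason above.

The interleaving is deliberate: multi-head attention slices the
channel axis into contiguous blocks, so interleaved pairs give every
head complete sine/cosine pairs over a band of scales. Two vector
encodings $f(p), f(m)$ then satisfy $f(p)\cdot f(m) =
\sum_k \cos((p-m)/s_k)$, a kernel sharply peaked at $p \approx m$ —
each head is a mass-matching detector at its own resolution band.

The precursor is fused as two extra encoder tokens (mass+m/z summed
encodings; a learned per-charge embedding, clamped at the table edge)
rather than added to every peak row, keeping peak rows pure.
Peak lists are truncated to the top 300 peaks by intensity for
bounded compute.

## The sequence-to-sequence model

A pre-norm transformer encoder/decoder (the full-scale design uses
ten layers of each; the desk default is two) trained by
teacher-forced cross-entropy with Adam. The implementation is a
compact, explicitly differentiated transformer in base R — at desk
dimensions (d = 64, 8 heads, feed-forward 256) BLAS-backed matrix
products make a framework unnecessary, and every backward pass is
pinned to finite differences in the test suite.

Four design choices matter far more than depth or width at this
scale, and all were settled empirically (held-out peptide recall on
the benchmark conditions; the rejected variants are noted because
they are instructive):

* **Prefix-mass fusion.** The decoder input at each step adds the
  sinusoidal encoding of the cumulative decoded residue mass. The
  next b-ion sits at (prefix mass + residue + proton), so with the
  kernel above, cross-attention can *locate* candidate peaks by phase
  comparison instead of having to learn mass arithmetic from token
  identities. Without it, held-out recall stalls near 50% while
  training loss keeps falling (memorisation).
* **Identity-seeded attention.** Q/K projections are initialised near
  the identity so attention logits start as the mass-matching kernel;
  gradient descent then refines offsets rather than having to
  discover the sin/cos pairing from a random basis.
* **Mass-offset attention biases.** Decoder cross-attention logits
  gain a learned weight per 0.25 Da bin of (peak m/z − ladder
  anchor), for two anchors per decoding step: the prefix-side ion
  (prefix + proton) and its complement (remaining mass + water +
  proton). This lets heads spotlight exactly the fragment ions whose
  presence or absence discriminates the next residue — the
  ion-matching evidence that earlier de novo tools computed as
  explicit features, here realised inside the transformer. It is the
  single largest contributor to held-out accuracy: without it,
  errors are dominated by adjacent-residue transpositions
  (mass-consistent sequences whose spectra differ in only two
  peaks) and recall plateaus well short of the benchmark level;
  with it those errors largely disappear.
* **No complement-mass fusion.** Adding the encoding of the
  *remaining* mass (precursor minus prefix) was tried and rejected:
  at step zero it equals the total residue mass, a near-unique
  fingerprint per training peptide, and the model promptly memorises
  — training loss halves while held-out recall collapses. The
  precursor tokens in the encoder carry the same information but
  evidently behind enough indirection not to become a shortcut.

Training normalises the loss by tokens per batch (not per peptide),
so long peptides — where errors concentrate — carry full weight.
Input-embedding dropout (default 0.1 in the benchmark, 0 otherwise)
is the only regulariser. Decoding direction is N→C by default
(C→N available as configuration). Maximum peptide length defaults to
40 tokens. Optimiser settings (Adam, lr $10^{-3}$ then $3\times
10^{-4}$, batch 16, gradient-norm clip 1.0) are ordinary choices and
all exposed.

## Knapsack-constrained beam search

The decoder is embedded in a beam search (width 5 by default) with a
hard admissibility rule: a residue $r$ may extend a hypothesis only
if the remaining mass (precursor residue mass − accumulated mass −
mass of $r$) lies, within tolerance, in a feasible bin of a knapsack
table; the end token is admissible only when the remaining mass
itself is within tolerance. The table is exact dynamic-programming
reachability over residue masses discretised at $10^{-4}$ Da
(Rcpp; the feasibility query allows ±1 bin of slack against edge
rounding). Consequently every completed hypothesis matches the
precursor neutral mass within tolerance *by construction* — the
mass-consistency guarantee is tested literally over a thousand
spectra with an untrained model, where it must still hold.

The decoding tolerance defaults to 0.1 Da on the neutral mass,
mirroring the residue-level matching tolerance; it is a flag. Ties
between equal-probability expansions break lexicographically by token
index, making runs deterministic. If no hypothesis can complete, the
result is empty with a diagnostic — never a mass-violating peptide.

Hypothesis confidence is $\exp(\text{mean per-token log
probability})$. With a rescorer attached: hypotheses classified decoy
are removed; highly detectable hypotheses rank ahead of potentially
detectable ones; and residues whose decoder log-probability falls in
the bottom decile of the peptide are masked and the language model's
proposal is accepted only if it preserves mass feasibility within
tolerance *and* raises the combined score (base confidence ×
(1 − P(decoy))). The combination rule is declared here rather than
inherited: the upstream description leaves it open.

## The peptide rescorer

A BERT-style encoder (stacked transformer encoder layers over residue
tokens plus a classification position) trained from scratch with two
heads: a masked language model and a 3-class detectability head
(decoy / highly detectable / potentially detectable). Corruption
follows the 7%/50% recipe: ceil(7% of positions) are selected, half
(rounded down) substituted with random residues, the rest replaced by
the mask token; the model restores the originals. Masking applies to
training only. Class imbalance is handled by inverse-frequency class
weights plus balanced class sampling. Detectability labels come from
observation frequency: targets at or above the 3rd quartile of the
group distribution are highly detectable, the rest potentially
detectable, decoys are always class 0. With all-equal frequencies
every target crosses the threshold — a degenerate case the labelling
function documents rather than hides.

Decoys are generated by shuffle (C-terminal residue fixed), free
shuffle, shuffle with cleavage-site conservation (K/R positions
fixed — an interpretation, flagged as such), and reverse (C-terminal
fixed). Sources whose permutation group is trivial (e.g. `AK` with
the cleavage site fixed) are returned unchanged but counted, so
callers can drop them; corpus construction keeps the decoy set
disjoint from targets.

Three training choices here were settled empirically and deserve
their rationale:

* **One imbalance correction, not two.** Inverse-frequency class
  weights *and* a balancing sampler, applied together, over-correct:
  the majority (decoy) class is simultaneously down-sampled and
  down-weighted, its share of the class gradient collapses to a few
  percent, and the decoy boundary never forms (held-out AUC stays at
  chance). `train_rescorer(balance=)` therefore applies balanced
  sampling by default — under which the effective class frequencies
  are equal and inverse-frequency weights reduce to 1 — with the
  weight-based and combined variants available as options.
* **Cost-sensitive decoy weight.** A decoy filter exists to enforce
  an asymmetry: calling a decoy detectable is worse than the
  reverse. `decoy_weight = 3` in the detectability study drives the
  residual decoy-as-highly-detectable rate to zero at desk scale
  without measurable AUC cost.
* **Mean-pooled classification and relative-position attention
  bias.** Detectability hinges on position-invariant local features
  (motifs). The classification head reads mean-pooled hidden states
  so every position feeds it directly, and attention logits carry a
  learned bias over clipped relative offsets so heads can attend
  "one position left" regardless of absolute position. Without
  both, the desk-scale classifier memorises training sequences
  instead of learning the motif: training AUC climbs while held-out
  AUC stays at chance.

## Assembly and protein inference

Predicted peptides become nodes of a confidence-weighted de Bruijn
graph (k-mers as nodes, (k+1)-mer overlaps as edges; node weight sums
the mean per-residue confidence over each occurrence window). Contigs
are extracted by greedy heaviest-path walks consuming visited nodes —
a simplified reimplementation of the external assembler stage's
input/output contract, not of its full scoring. k defaults to 7; the
source material states 7 in the methods and 8 in a table caption (a
genuine internal inconsistency), so both are one flag away. I and L
are collapsed to L before assembly by default (identical masses would
otherwise create artificial branch points).

Contigs map to proteins by k-mer candidate search (k = 5): candidates
ranked by the number of shared unique k-mers (U), examined in
decreasing U order, scored by best local alignment (match +1,
mismatch −1, linear gap −2, via Biostrings); a candidate at or above
80% identity is a hit, and scanning stops after 8 consecutive
rejects. Protein inference then iterates: (a) provisional score =
sum of associated unassigned contig scores, (b) best protein takes
its contigs (ties break lexicographically by accession for
determinism), (c) proteins left without possible contigs become
subsets of the protein last assigned, (d) repeat until all contigs
are assigned. Scores are recomputed over the remaining contigs each
round — our reading of "repeat steps a–c"; a `recompute = FALSE`
switch freezes round-1 scores for the other reading. An independent
brute-force simulator of the same four steps cross-checks the
implementation on random bipartite instances in the tests. The
protein report counts only contigs aligning at ≥ 80% identity and
reports coverage (% protein positions covered) and accuracy
(% aligned calls that match).

## Evaluation metrics

A predicted residue matches a true residue when their masses differ
by less than 0.1 Da *and* their prefix masses (sum of residue masses
before the position) differ by less than 0.5 Da. The match count is
defined as the maximum order-preserving matching under both
constraints, computed by dynamic programming and cross-checked
against exhaustive enumeration of all monotone matchings at small
lengths. A peptide-level match requires every true residue matched
*and* equal lengths (the stricter reading; stated explicitly because
the source leaves it implicit). Amino-acid recall divides total
matches by total true length; precision by total predicted length;
peptide-level analogues count spectra. With no predictions emitted,
precision is reported as 0 and flagged. Precision–recall curves sweep
every distinct confidence value as a threshold.

## What the synthetic data does and does not show

The generator emulates the *error structure* of real data, not its
physics. Defaults were set once from the reported error statistics:
each theoretical fragment peak is dropped with probability 0.125
(leaving ~91% of typical tryptic spectra missing at least one ion)
and noise peaks are added at 5.25 per observed signal peak (~84% of
peaks are noise), uniform in m/z, with intensities drawn below the
median signal intensity — mirroring the convention that labels a peak
noise when it falls under the set median. Signal intensities are
log-normal and carry no information about the residue sequence;
retention time and realistic fragment-intensity prediction are out of
scope.

Peptides sampled for model corpora carry one planted motif each
(`peptide_motif_prob = 1`). This is deliberate: uniformly random
peptides are statistically indistinguishable from their own shuffles,
so no detectability model — at any scale — could separate targets
from decoys on such a population. The motif gives the synthetic
peptide population the compositional bias real observable peptides
have, which is exactly what the rescorer is supposed to exploit.

The detectability corpus adds three structural choices. The
full-alphabet motifs are 6-mers: shorter motifs reappear too easily
inside shuffled decoys of motif-rich peptides, blurring the class
boundary that the corpus exists to make learnable. The boosted
motif's prevalence is kept near 25% of targets (`motif_weights`), so
the 3rd-quartile labelling cut falls at the gap between boosted and
unboosted frequency distributions and the class labels are nearly
deterministic in the motif — and, matching the full-scale corpus
shape, the highly detectable class stays the minority. Finally,
decoys that happen to retain an intact planted motif are excluded:
a "decoy" carrying the very structure that defines detectability is
not a negative control (at proteome scale such collisions are
vanishingly rare; at desk scale they must be filtered).
Consequently, passing tests demonstrate that the machinery works and
interacts correctly (mass constraints, ranking, refinement,
assembly), *not* that the desk models would reach any particular
accuracy on real spectra: real noise is structured, real
detectability depends on physicochemistry rather than a motif, and
real training corpora are orders of magnitude larger.

The benchmark study (`desk_benchmark()`) uses 2000 noise-free
reduced-alphabet (G/A/S/V/L) training spectra, 200 held-out spectra,
a 2+2-layer model (d = 64, 8 heads, feed-forward 256, dropout 0.1,
17 epochs with one learning-rate drop) and beam width 5 — sizes
chosen so the whole study trains and evaluates in minutes on one
core; the reduced alphabet keeps spectra uniquely decodable while
shrinking the hypothesis space enough for a from-scratch model to
generalise from 2000 examples. The detectability study digests a
240-protein synthetic proteome (~1500 targets, ~4:1 decoys) and
trains a d = 32, 2-layer rescorer for 20 epochs.

Its observation model matters: a peptide universe receives simulated
observation frequencies (boosted for peptides carrying the first
planted motif), and the *observed* spectrum corpus is drawn from the
highly detectable pool with probability proportional to frequency.
Observed spectra therefore come from highly detectable peptides —
which is what detectability means. Under a uniform observation model the
detectability labels are statistically independent of which beam
hypothesis is correct, and the rank rule "highly detectable first"
can only inject noise; under the frequency-weighted model the rule
promotes correct hypotheses, which is the mechanism the rescorer
exists to exploit.

## Numerical and degenerate-case choices

* Knapsack bins: $10^{-4}$ Da, ±1 bin slack at query time; bin 0
  always feasible (empty multiset).
* Proton 1.007276 Da everywhere charge and mass interconvert; water
  18.010565 Da; masses stored to six decimals.
* Empty spectra, empty graphs, empty candidate lists and empty
  prediction sets all return typed empty results, not errors;
  records that cannot be parsed are skipped with named warnings.
* Missing precursor charge is imputed as 2+ (most tryptic precursors)
  and flagged on the record.
* FASTA residues B/Z/X/U are kept in sequences for alignment but
  excluded from k-mer indexing (avoids fake seed matches).
* Checkpoints store weights, both configurations, optimiser state and
  a vocabulary hash; training refuses data whose peptides do not
  tokenise under the model vocabulary.

## Known limitations

* The transformer is desk-scale; no attempt is made to reproduce
  full-scale trained weights or external benchmark figures.
* The assembler is a greedy heaviest-path extraction, not the full
  external assembler algorithm it stands in for.
* DIA spectra, vendor raw formats, isotope envelopes, neutral-loss
  series and protein-level FDR are out of scope.
* Masked refinement is conservative by design (mass-preserving,
  score-raising substitutions only); on the reduced alphabet no
  single-residue substitution is mass-preserving, so refinement is a
  no-op there.
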