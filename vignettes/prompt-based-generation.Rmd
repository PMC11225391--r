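---
title: "Prompt-based constrained molecule generation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prompt-based constrained molecule generation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A chemical language model (CLM) trained on plain SMILES generates molecules
token by token, left to right, from a GO token until it emits EOS. Medicinal
chemistry frequently needs *constrained* generation instead: decorate a fixed
scaffold at marked positions, or connect two or more fixed fragments with a
de novo linker. The usual answer is a bespoke architecture (an
encoder–decoder trained on sliced datasets, a custom grammar, a graph
model). This package implements the alternative: keep one ordinary
decoder-only CLM and move all of the work into SMILES string rearrangement,
so the same pre-trained model performs de novo generation, scaffold
decoration, and fragment linking.

Two facts make this possible. First, autoregressive generation extends the
*end* of the string, so if a molecule is rewritten such that the chosen
attachment atom is the **last** atom token, sampling continues growth exactly
there. Second, a molecule has many valid SMILES; the traversal root and
branch order are free choices, so such a rewriting always exists (up to the
caveats below).

## String algebra

Attachment points are dummy atoms `*`, written `(*)` in branch form (bare
terminal `*` is accepted and handled equivalently). The machinery, all
exported:

* `parse_attachment_points()` — locate markers, check each is bonded to
  exactly one real atom with free valence, and derive the core (markers
  removed).
* `strip_markers()` / `reinsert_markers()` — remove markers while recording
  character spans, so that after a completion is *appended* to the prompt the
  remaining markers can be re-inserted at their original positions. This is
  exact string inversion because generation only ever modifies the string
  after the prompt.
* `root_at_atom()` — rewrite the SMILES so a chosen atom is the first token
  (deterministic traversal, or randomized for variant enumeration).
* `reverse_smiles()` — rewrite so the first atom becomes the *last* atom
  token. This is a unit-level reversal: each main-chain atom keeps its ring
  closure digits and branch groups, bonds stay between the same atom pairs,
  and the chain order is flipped. Branches hanging off the old root cannot
  follow it (nothing may follow the last atom), so they are hoisted into
  leading dot-components reconnected through fresh ring-closure digits:
  `C(C)C` reversed at the middle carbon becomes `C1.CC1`, a valid SMILES for
  propane whose final atom is the middle carbon. If construction fails
  self-verification, a rejection-sampling fallback over randomized rooted
  forms is tried; only then is a reversal failure raised.
* `insert_branch()` — graft a fragment (rooted at its attachment atom) as a
  parenthesised branch at a host atom, renumbering the fragment's ring
  digits to digits unused in the host so rings can never silently fuse.

Open Babel (via ChemmineR/ChemmineOB) supplies canonical SMILES, which the
package uses as its graph-isomorphism test, plus SMARTS matching and
fingerprints. The parser, writer, reversal and marker bookkeeping are native
to the package: these rearrangements are its entire point, and they must
operate at the *string* level with full control of atom order and character
spans.

## The generation algorithms

**Scaffold decoration.** Repeat until no markers remain: select a marker
(`canonical` = first in appearance order; `shuffle` = uniformly at random, so
a batch mixes orders); remove it; root + reverse the molecule at its
attachment atom; strip remaining markers (recording the ledger); let the CLM
extend the string until EOS; re-insert the markers. An immediate EOS is
legal and leaves the site hydrogen-capped. Each iteration requires a
parseable intermediate molecule; consequently decorations cannot *open* a
ring at one attachment point and close it at another — a documented
limitation, not an accident.

**Two-fragment linking.** One fragment (canonical or shuffled order) is
rooted + reversed into the prompt; the CLM samples a linker until EOS; the
second fragment is rooted so its attachment atom comes *first* (not
reversed) and simply concatenated, with its ring digits renumbered against
the prompt + linker. An empty linker yields a direct bond.

**Multi-fragment linking (3+).** The initial fragment is rooted, reversed,
and completed into a full molecule by the CLM. Each remaining fragment is
then inserted at the candidate atom (free valence, not already belonging to
a placed fragment) whose `insert_branch()` result has the *lowest full-
sequence NLL* under the CLM — an exhaustive scan, ties to the lowest atom
index. If the molecule already contains the fragment's core, insertion is
skipped and the matched atoms are claimed instead (during RL the model
learns to produce the fragments itself). Because every placed fragment's
atoms become forbidden for later insertions, branched (non-linear) linking
topologies arise naturally.

**Prompt optimisation (`optimise`).** Instead of the single deterministic
rooted + reversed form, up to `k_variants` (default 10) distinct randomized
variants are enumerated and the one with the lowest prompt NLL (scored as an
open prefix, without the EOS term) is used — the rearrangement the CLM finds
most natural. Variant deduplication is by exact string equality, not by
graph, because the CLM scores strings.

## The language model

A compact GRU language model written against base-R matrix algebra:
embedding, one or more GRU layers, a softmax head; teacher-forced training
with Adam; autoregressive sampling with per-row prompts (prompt tokens are
forced, then free sampling until EOS). The recurrence is

    r = σ(W_r x + b_r + U_r h),  z = σ(W_z x + b_z + U_z h),
    n = tanh(W_n x + b_n + r ∘ (U_n h)),  h' = (1 − z) ∘ n + z ∘ h,

with gradients verified against numerical differentiation in the test
suite. Likelihoods are reported in nats; `clm_nll()` is the exact sum of
per-step −log P(token | prefix), and the sampler's accumulated
log-probabilities agree with it bit-for-bit (special tokens are excluded
from the sampling draw but not from the probability model, so the recorded
likelihood of the drawn sequence is unchanged).

Default profile: 1 layer, hidden 160, embedding 64, learning rate 3e-3,
batch 64, 5 epochs. This is sized for the synthetic corpus below and for
CPU-only use; every contract here is architecture-agnostic, and all sizes
are arguments. The prompting layer talks to the model only through two
callbacks — a prompted sampler and a string NLL (`clm_callbacks()`) — so any
other implementation with those two operations can be substituted.

## Reinforcement learning

The REINVENT scheme: a frozen *prior* (the pre-trained model) and a
trainable *agent*. Each step first *collects* a batch of molecules through
the chosen generation mode without gradient bookkeeping, computes rewards in
[0, 1] **on the completed molecules**, and then performs one Adam step on

    L = mean_i [ (−NLL_prior(s_i) + σ·r_i) − (−NLL_agent(s_i)) ]²,

with σ = 120. The update sequences depend on the mode: `single` uses one
designated sequence per molecule — the completed SMILES for decoration, but
the *initial fragment + de novo linker* for fragment linking, because
scoring the concatenated molecule would teach the model to generate the
fixed fragments itself; `multi` applies one update per prompt-completion
iteration record, each with the molecule's final reward, and recomputes the
prior likelihood per record (the alternative — reusing the final-sequence
prior — is ambiguous in the scheme this follows; per-record is the
self-consistent choice). Likelihoods cover all tokens including the prompt;
a `mask_prompt` flag restricts the loss to generated tokens (default off).

RL defaults: lr 1e-4 is the config default for general use; the toy-scale
experiments in the tests and the acceptance script pass lr 5e-4 and batch
24, which on the two-site scaffold lifts uniqueness by well over ten
percentage points within 60 steps. An occurrence-count diversity filter
(`diversity_penalty()`) keyed on a pruned generic framework (iteratively
removing terminal atoms; the canonical SMILES itself for acyclic molecules)
is available but off by default.

Rewards shipped: binary valid + unique (with an explicit run memory),
Tanimoto similarity on Open Babel ECFP4 circular fingerprints (plain
intersection-over-union, no add-one smoothing), linker length / linearity /
flexibility with band rewards, and a weighted-mean pipeline accepting
arbitrary external scorers (any function SMILES → [0, 1]).

*Linker properties.* Fragment atoms are identified by VF2 subgraph matching
(element + aromaticity vertex colours, order + aromaticity edge colours)
with the disjoint placement maximizing covered atoms; the linker is
everything else. Flexibility is the fraction of linker-internal bonds that
are rotatable (acyclic single bonds between non-terminal heavy atoms).
Linearity — for which no community-standard formula exists — is defined here
as (atoms on the shortest junction-to-junction path) / (linker atoms), 1
for an unbranched acyclic linker and, by convention, 1 for an empty linker
with flexibility 0.

## The synthetic corpus

`generate_corpus()` grows random molecular graphs — chain-biased acyclic
growth over C/N/O/F/S with occasional double bonds, plus benzene, pyridine,
cyclopentane and cyclohexane ring templates — and writes them with the
package's writer rooted at a chain end, side chains first. Molecules have
5–14 heavy atoms, a ≤ 40-token vocabulary, and are valid by construction
(and re-checked). The standard study conditions used throughout the tests
and the acceptance script are a 5,000-molecule corpus (seed-deterministic)
and the default model profile trained 5 epochs, which yields roughly 90%
valid de novo SMILES — enough head-room above the 80% gate that downstream
stochastic tests rely on.

What the generator does *not* emulate: real property distributions
(lipophilicity, ring-system diversity), stereochemistry, charged species,
or the long-tail grammar of ChEMBL-scale data. Tests passing on this corpus
demonstrate the correctness of the string algebra, the prompting mechanics,
and the RL plumbing — they are not evidence about chemistry-space coverage
of any real training set.

## Numerical and design choices

* **Atom indexing** is 0-based over atom appearance order in the string;
  character spans are half-open. Ring-digit renumbering always takes the
  lowest digits unused in the host, using `%nn` above 9.
* **Validity** means: the native parser accepts the string (syntax, ring
  closure completeness, a standard valence model with charge adjustments)
  *and* Open Babel canonicalizes it. Aromatic nitrogen gaining a substituent
  trades its π contribution for the lone pair (pyridine-type →
  pyrrole-type), which is how a marker on a pyridine-like nitrogen is
  admitted.
* **Containment checks** (the decoration/linking constraint) are VF2 graph
  matches on the *written* structure, with aromaticity as written. Toolkit
  SMARTS matching (`is_substructure()`, markers as wildcards) is exposed
  too, but re-perceives aromaticity and therefore rejects exotic rings that
  the string-level construction demonstrably preserved.
* **Stereochemistry** is accepted on input and dropped: the package operates
  on constitution only. (Rooted writing that preserves stereo would need a
  toolkit-grade canonical writer, which is out of scope here.)
* **Unterminated completions** (max-length without EOS) mark the attempt
  invalid rather than being silently truncated.
* **Insertion scoring uses raw total NLL**, not length-normalized — this
  biases toward shorter candidates and is flagged as such, matching the
  ambiguity in the scheme this implements.
* **Ties** in likelihood selections break to the first candidate / lowest
  atom index, making all selections deterministic given the model.

## Known limitations

* No ring formation across decoration iterations (each intermediate must
  parse), hence no macrocyclisation through two attachment points.
* Attachment bonds are single bonds; bond-order-specified or
  stereo-locked junctions are unsupported.
* Mid-chain attachment atoms are reachable only through dot-component
  reversal, which is valid SMILES but out-of-distribution for a CLM trained
  on plain molecules; expect lower completion quality there.
* The GRU is CPU-sized; nothing prevents wiring the prompting layer to a
  larger external model through `clm_callbacks()`-shaped functions.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` use: 1,000 molecules for the
string-algebra properties; 300 attempts each for decoration and pair
linking; 50 + 50 instances for the likelihood-selection oracle comparisons;
batches of 1,000 decorated molecules before and after 60 RL steps (batch 24)
for the uniqueness-rescue experiment; and 120 attempts per condition for the
fragment-count similarity sweep. These sizes were chosen so the whole
pipeline — corpus, training, generation, RL — reruns from scratch on a single
CPU core while keeping the stochastic margins (validity head-room, rescue
gain, similarity ordering) far from their thresholds.
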