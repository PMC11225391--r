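# promptclm

Constrained molecule generation with a single decoder-only chemical
language model (CLM), for computational and medicinal chemists who need
**scaffold decoration** and **fragment linking** without training bespoke
encoder–decoder architectures or custom grammars.

A CLM trained on plain SMILES extends strings at their end. The trick is
therefore pure string algebra: rewrite the molecule so the attachment atom
of interest is the **last atom token** of the SMILES, let the model
continue the string, and book-keep the remaining attachment markers across
iterations. With the usual notation — a scaffold *S* carrying attachment
points *A* as dummy atoms `(*)`, e.g. a meta-substituted benzene
`c1c(*)cc(*)cc1` — one pre-trained model then covers:

* **de novo generation** — plain sampling, `x_t ~ P(x_t | x_<t)`;
* **scaffold decoration** — per attachment point: root the SMILES at the
  attachment atom, reverse it so that atom is last, strip the other
  markers (recording their character spans), sample until EOS, re-insert
  the markers; iterate until no markers remain;
* **two-fragment linking** — fragment 1 rooted + reversed as the prompt, a
  de novo linker sampled, fragment 2 rooted attachment-atom-first and
  concatenated;
* **multi-fragment linking** — the CLM completes the first fragment into a
  molecule; each further fragment is grafted at the insertion atom giving
  the highest full-sequence likelihood (skipping fragments the model
  already generated), previously placed fragments excluded — branched
  topologies included;
* **reinforcement learning** — REINVENT-style augmented likelihood
  `L = mean[((-NLL_prior + σ·r) - (-NLL_agent))²]` with σ = 120, rewards in
  [0, 1] computed on completed molecules, single or per-iteration (multi)
  updates, which adapts the model to the iterative prompting regime and to
  arbitrary objectives (validity/uniqueness, fingerprint similarity,
  linker length/linearity/flexibility).

The package ships a compact GRU chemical language model (base-R matrix
algebra, CPU-only, gradient-checked), a seeded synthetic SMILES corpus
generator so everything runs without downloads, the full SMILES
rearrangement toolkit (`parse_attachment_points`, `root_at_atom`,
`reverse_smiles`, `insert_branch`, ...), and a command-line interface
(`inst/cli/promptclm`). Open Babel (ChemmineR/ChemmineOB) provides
canonicalization, SMARTS matching and fingerprints; igraph provides
subgraph matching.

## Worked example

```r
library(promptclm)

corpus <- generate_corpus(5000, seed = 7)        # synthetic drug-like-ish SMILES
model  <- clm(corpus, epochs = 5, seed = 3, verbose = TRUE)
#> epoch 1: mean token NLL 1.5582
#> epoch 2: mean token NLL 1.0265
#> epoch 3: mean token NLL 0.9471
#> epoch 4: mean token NLL 0.9104
#> epoch 5: mean token NLL 0.8925

clm_sample(model, n = 5, max_len = 60, seed = 1)$smiles
#> [1] "C=CC(C)OONC"       "C=COC"             "CNC1CCCC1CCCCO"
#> [4] "FCCCC(C)Cc1ncccc1" "CCc1ccccc1"
```

The mean token NLL (nats) falls as the model learns the corpus grammar;
at this size about 88% of 1,000 de novo samples are valid SMILES.
Decoration keeps the scaffold and substitutes every marked position:

```r
decorate(model, "c1c(*)cc(*)cc1", n = 5, seed = 1)
#> <generation_set> decorate: 5 attempts, 40.0% valid
#>                        smiles valid iterations
#>         COCCC=C(C)c(ccc1)cc1N  TRUE          2
#>                          <NA> FALSE          2
#>  c1ccccc1nc(ccc1)cc1c1ncccc1C  TRUE          2
#>  ...
```

Every valid result contains the benzene core with both meta positions
extended (two iterations = two attachment points). Linking the fragment
pair `C1C(*)C1` / `n1(*)ccncc1` prompts with the reversed cyclopropane,
samples a linker, and concatenates the pyrazine head-first:

```r
lnk <- link_pair(model, toy_cases()$pair, n = 10, seed = 4)
lnk$summary[lnk$summary$valid, ]
#>                          smiles valid iterations
#> 2  C1CC1CC1CC(C(F)C)CC1n2ccncc2  TRUE          1
#> 5     C1CC1CC(C)c1nccc1n2ccncc2  TRUE          1
#> 6 C1CC1CC(=CC)CCC1CCCC1n2ccncc2  TRUE          1
```

Low pre-RL validity and uniqueness are expected — after the first
iteration the model tends to consider the molecule complete — and this is
exactly what the RL loop repairs. With the binary valid + unique reward on
the two-site scaffold, 60 RL steps (batch 24, σ = 120) raise the unique
fraction of a 1,000-sample batch by well over ten percentage points across
seeds while keeping validity:

```r
mem <- reward_memory()
out <- rl_optimize(model, rl_task_decorate("c1c(*)cc(*)cc1"),
                   function(s) valid_unique_reward(s, mem),
                   rl_config(sigma = 120, batch_size = 24, steps = 60,
                             lr = 5e-4, seed = 11))
```

The same checkpoint switches between de novo sampling, `decorate()`,
`link_pair()` / `link_multi()` and `rl_optimize()` — only the call changes,
never the model. See `vignettes/prompt-based-generation.Rmd` for the
algorithms, parameter choices and limitations.

## Command line

```sh
promptclm fixtures make-corpus -n 5000 -o corpus.smi --seed 7
promptclm pretrain corpus.smi -o ckpt.rds --epochs 5 --seed 3
promptclm sample   ckpt.rds -n 1000 -o out/
promptclm decorate ckpt.rds --scaffold "c1c(*)cc(*)cc1" --strategy shuffle --optimise -n 1000 -o out/
promptclm link     ckpt.rds --fragments "C1C(*)C1,n1(*)ccncc1" -n 1000 -o out/
promptclm optimize ckpt.rds --scaffold "c1c(*)cc(*)cc1" --reward valid_unique --steps 100 -o out/
```

`link` dispatches the two-fragment or multi-fragment algorithm by fragment
count; every run writes a manifest (config echo, seed, package version)
sufficient to reproduce it.

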