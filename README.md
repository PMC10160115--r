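# stimdecode

Sentiment decoding from naturalistic movie-watching fMRI, starting from
nothing but the movie's word-level subtitle annotations.

## The problem

During free movie viewing there is no trial structure to decode, so labels
must come from the stimulus itself. `stimdecode` implements the complete
stimulus-to-label-to-decoder chain used in naturalistic multi-voxel pattern
analysis (MVPA) of sentiment:

1. **Annotations → sentences.** Word-annotation tables (word, onset s,
   offset s, sentence-end marker) are parsed and reassembled into timed
   sentences; corpus statistics (length/duration moments) characterise the
   subtitle stream.
2. **Sentences → sentiment labels.** Each sentence gets a lexicon-based
   *compound score*: with word valences summed into S (a negation word
   within 3 tokens before a lexicon word multiplies its valence by −0.74),

   compound = S / √(S² + α),  α = 15,

   bounded in (−1, +1); its sign is the polarity (+, −, or exactly 0 =
   neutral). Three class schemes fold the neutral class: Binary Case 1
   (neutral → positive), Binary Case 2 (neutral → negative), or a 3-class
   case. Label vectors from different analyzers are compared with an
   element-wise agreement count S₁₂ = Σᵢ 1[v₁ᵢ = v₂ᵢ].
3. **Labels → TR grid.** Each sentence claims ⌈duration / TR⌉ fMRI volumes
   from its onset volume (an 8.3 s sentence at TR = 1 s labels nine
   volumes); silence gaps carry the previous label forward; an
   un-annotated lead-in (e.g. 61 s of 1805 volumes, leaving 1744) is
   discarded.
4. **Volumes → features.** Voxels within 5 mm spheres around MNI seed
   coordinates are extracted from 4D NIfTI images (or pre-extracted TSV
   time series) and stacked across subjects into a labeled matrix — with
   20 subjects, 1744 volumes and 111 ROI voxels, a 34,880 × 112 matrix.
5. **Balancing and decoding.** Classes are equalized by random
   oversampling (ROS) or SMOTE; sentiments are classified with random
   forest, RBF-SVM, decision tree, or a 7-hidden-layer ReLU MLP
   (100-90-70-50-30-20-10, logistic/softmax head, Adam), evaluated by
   70/20/10 hold-out or 10-fold cross-validation, with shuffled-label runs
   giving the empirical chance level.

A synthetic generator produces annotation streams with known sentence
polarities and fMRI-like voxel data with a configurable class effect size
*d* (per-voxel class mean shift in noise-sd units), so every stage runs and
is testable offline.

## Worked example

```r
library(stimdecode)

# lexicon scoring with negation handling
s <- score_sentence("did not love the ending", read_lexicon())
# compound = -0.5216, raw sum = -2.368, polarity = -1

# synthetic end-to-end run: 4 subjects, 400 volumes, weak signal d = 0.1
cfg <- synth_config(n_subjects = 4, n_volumes = 400, d = 0.1, seed = 42)
run <- run_pipeline(list(synth = cfg, case = "binary1", model = "rf",
                         balance = "ros",
                         seeds = list(split_seed = 1, balance_seed = 1,
                                      model_seed = 1)),
                    out_dir = "demo_run")
print(run)
#> Pipeline run: rf / binary1 / balance=ros | feature matrix 1600 x 112
#> Evaluation on 558 samples
#>   accuracy 0.995 | macro precision 0.995 | recall 0.995 | F1 0.995
```

The 0.995 is *inflated*: by default ROS duplicates minority rows before
the train/test split, so copies of the same row land on both sides — the
same run with `balance = "none"` scores 0.875. The pipeline keeps the
oversample-then-split order as its default because that is the procedure
it models, and documents the leakage; pass the balanced data through
`balance_classes()` on the training partition only for the leakage-free
variant. Shuffled-label controls (`shuffle = TRUE`) fall to ≈ 0.50
(binary) / ≈ 0.33 (3-class) on balanced data.

Intermediate artifacts (sentences, per-sentence labels, per-volume labels,
the feature matrix, report and manifest with MD5 hashes) are written to
`out_dir`. A thin CLI over the same functions is installed at
`inst/scripts/stimdecode` (subcommands `label`, `similarity`, `align`,
`synth`, `run`).

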