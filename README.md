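# tpssan — two-view semi-supervised attention networks for 3D cardiac segmentation

`tpssan` is an R toolkit for semi-supervised segmentation of 3D cardiac
volumes: situations where a few scans carry voxel-wise expert labels and
many more do not. It trains a **mean-teacher** pair of VNet-style networks —
a student updated by SGD, a teacher updated as an exponential moving
average (θ_t ← d·θ_t + (1−d)·θ_s) that supplies pseudo-labels on noised
unlabeled inputs — with three additions aimed at small labeled pools:

* **Two-view slice-confidence supervision.** The middle transverse and
  middle coronal slices act as source slices; a slice at index distance
  *d* receives confidence `weight^d` (1 at the source, exponential decay
  elsewhere). The two per-view maps are fused voxelwise (product by
  default) into a weight map *W* that enters both losses:
  `L_ce = −Σ w_i log p_i[y_i] / Σ w_i` and
  `L_dice = 1 − 2 Σ w_i y_i p_i / Σ w_i (p_i² + y_i²)`.
* **3D CutMix.** Unlabeled patch pairs are mixed by a box mask M,
  `x̃ = M·x_A + (1−M)·x_B`, with λ ~ Beta(1, 1) and the teacher's
  pseudo-labels mixed by the same mask.
* **Uncertainty-rectified multi-scale consistency.** The network (CBAP-VNet:
  a residual VNet with CBAM channel+spatial attention on the downsampling
  blocks and an adaptive channel-attention gate at the input stem) emits S
  prediction heads p_0…p_{S−1}; per scale, the voxelwise KL divergence
  `D_s = Σ_j p_s^j log(p_s^j / p_c^j)` against the scale average p_c
  down-weights the consistency penalty by `exp(−D_s)` and is itself
  minimized. The total loss is `L_sup + L_semi + λ(t)·L_unsup` with a
  Gaussian ramp on λ.

A cardiac **phantom simulator** (bright ellipsoidal chamber with tubular
appendages, bias field, Gaussian noise) makes the entire pipeline — data,
training, sliding-window inference, and Dice/Jaccard/95HD/ASD evaluation —
runnable on a single CPU with no external dataset. The network and its
gradients run on a compact reverse-mode autodiff engine with C++ kernels
included in the package.

## Worked example

```r
library(tpssan)

# simulate 2 labeled + 8 unlabeled training phantoms and 3 test phantoms,
# train the full framework, predict the test volumes, evaluate:
res <- run_demo("demo", seed = 1, mode = "full")
res$report
#>                  case     dice  jaccard hd95       asd
#> 1 case_001_lab.nii.gz 96.40206 93.05402    1 0.1680261
#> 2 case_002_lab.nii.gz 96.24146 92.75521    1 0.1845775
#> 3 case_003_lab.nii.gz 97.39229 94.91713    1 0.1235772
#> 4                mean 96.67860 93.57546    1 0.1587270
```

Each row is one held-out phantom: `dice`/`jaccard` are overlap percentages
between the predicted and true chamber masks, `hd95` the 95th-percentile
surface distance and `asd` the mean surface distance in voxel units (both
≈ 0.1–1 voxel here, i.e. the predicted boundary is essentially correct).
The per-iteration loss log (`res$log_csv`) shows the supervised loss
falling from 1.026 to 0.027 over the 120-iteration demo schedule while the
consistency weight λ ramps from 0 to 0.1.

`mode = "sup_only"` trains the plain-VNet supervised baseline on the same
data for the ablation comparison, and `make_variant(1..5)` selects the five
attention-placement variants (3 = the proposed CBAP-VNet).

A command-line interface wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","tpssan.R",package="tpssan"))') \
    demo --workdir demo --seed 1
# subcommands: simulate / train / predict / evaluate / demo
```

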