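# treeparse3d

Individual-tree instance segmentation and structural phenotyping for
densely planted plantation point clouds, with a built-in synthetic
rubber-plantation generator so the whole pipeline runs and is tested
without external data.

## The problem

UAV LiDAR over managed plantations (the motivating system is rubber,
*Hevea brasiliensis*) produces point clouds in which adjacent crowns
interpenetrate along the planting row, density drops steeply from the
closed canopy to the trunk space, and young and mature trees coexist.
Separating such clouds into individual trees — and then measuring each
tree's height, crown diameter and crown volume — requires more than
geometry-only clustering.

`treeparse3d` implements a multimodal pipeline:

- **Boundary-guided multimodal encoding.** Top-view crown polygons
  (LabelMe-style JSON) are encoded to a semantic vector
  *F<sub>s</sub>*, expanded into an 8-vertex hypercube feature template
  *H<sub>s</sub>* ∈ ℝ<sup>8×D</sup>, and fused onto every point by its
  trilinear weights *w*<sub>1..8</sub> over the block-normalized unit
  cube (*F*<sub>fused</sub> = *W*<sub>interp</sub>*H*<sub>s</sub>), then
  refined by branch selection (softmax), sparse gating (retain points
  with gate score > τ<sub>g</sub>), subspace entanglement
  (*Q<sub>j</sub>* = N<sup>−1</sup>Σ<sub>i</sub> q<sub>ij</sub>q<sub>ij</sub><sup>T</sup>)
  and a dynamic convolution with coordinate residual.
- **Z-order serialized selective scan.** Voxelized points are ordered by
  Morton code (bit interleaving of voxel coordinates), run through a
  selective state-space recurrence
  *x<sub>t</sub>* = e<sup>Δ<sub>t</sub>A</sup>*x*<sub>t−1</sub> + Δ<sub>t</sub>*B<sub>t</sub>u<sub>t</sub>*,
  *y<sub>t</sub>* = *C<sub>t</sub>x<sub>t</sub>* + *Du<sub>t</sub>*
  (Δ<sub>t</sub> = softplus of a linear projection of the input), RMS
  normalization, and exact inverse reordering.
- **Adaptive clustering.** Crown points are clustered by a size-aware
  backend (kNN connectivity for small segments, 2D flat-kernel mean
  shift for large ones) whose hyperparameters are searched by a
  lemming-style metaheuristic: Lévy-flight exploration (β = 1.5), DS/GFT
  exploitation and spiral refinement once the control factor
  E = 2 ln(1/u)·2 arctan(1 − t/T) drops below 1, accepting a candidate
  only when the feedback score 0.7·mean F₁ + 0.3·max F₁ beats the
  incumbent.
- **Metrics and structural parameters.** Semantic mIoU; one-to-one
  instance matching at IoU ≥ τ with precision/recall/F-score and
  all-point average precision; per-tree height (max z above ground),
  crown diameter (equal-area-circle of the XY hull) and voxel-occupancy
  crown volume, with R²/RMSE agreement reports.

Everything is tibble-first: point clouds are tibbles, results have
`tidy()` / `glance()` methods and `autoplot()` figures, so calls chain
with the pipe.

## Worked example

```r
library(treeparse3d)

gen <- generate_plantation(plantation_spec(rows = 2, trees_per_row = 3, seed = 42))
gen$pc
#> # Point cloud: 6860 points, 6761 crown, 6 instances

fit <- optimize_clustering(gen$pc,
                           make_supervised_scorer(gen$pc$instance, tau = 0.5),
                           max_iter = 30, seed = 42)
glance(fit)
#> # A tibble: 1 × 5
#>   backend   best_score n_instances theta1 theta2
#>   <chr>          <dbl>       <int>  <dbl>  <dbl>
#> 1 meanshift          1           6   1.45   22.8

evaluate_segmentation(gen$pc$semantic, gen$pc$semantic,
                      fit$instance, gen$pc$instance)
#> # Segmentation evaluation (IoU tau = 0.50)
#>   mIoU 1.0000 | P 1.0000 R 1.0000 F 1.0000 AP 1.0000

tm <- extract_metrics(gen$pc)
glance(agreement(tm, gen$ground_truth))["r_squared_height"]
#> # A tibble: 1 × 1
#>   r_squared_height
#>              <dbl>
#> 1                1
```

The six trees of the synthetic block are recovered exactly (best
feedback score 1 with a mean-shift bandwidth of about 1.45 m), the
instance F-score and AP at IoU 0.5 are 1, and extracted tree heights
match the generator's ground truth (R² = 1, RMSE = 0 on noiseless max-z
heights). On harder blocks (stronger overlap, more trees) the search
typically lands at F-scores of 0.95–1 within 50 iterations.

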