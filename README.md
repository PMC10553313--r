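# pestcascade

Fine-grained recognition of agricultural pests: many species look alike,
the evidence that separates them is confined to a small body region, and
field photographs bury that region in clutter. `pestcascade` implements a
three-scale recurrent-attention convolutional cascade for this problem,
with a synthetic planted-patch benchmark so the whole pipeline can be
exercised and tested on a single CPU.

## The method

Each scale `m = 1, 2, 3` pairs a five-stage VGG-style backbone with two
outputs:

* five pooling-level class predictions `P1..P5` (one per pooling stage,
  via global average pooling, an affine map and softmax), with `P5`
  serving as the scale's prediction `Y^(m)`;
* an attention proposal: a square region with centre `(tx, ty)` and half
  side `tl`, corners `(tx − tl, ty − tl)` and `(tx + tl, ty + tl)`.

The proposed region is cut out by elementwise multiplication with a
separable soft-boxcar mask

```
M(x, y) = [H(x − tx_tl) − H(x − tx_br)] · [H(y − ty_tl) − H(y − ty_br)]
```

(`H` a logistic approximation to the step function), bilinearly zoomed to
the network input size, and fed to the next scale. Because mask and
sampling grid are smooth in `(tx, ty, tl)`, the crop is differentiable
and classification gradients steer the attention head: `∂M/∂tx` is
negative approaching the left edge, positive approaching the right edge,
and zero elsewhere.

Training minimises

```
L = Σ_{m=1..3} Lcls(Y^(m), Y*) + Σ_{m=1..2} Lrank(Pt(m), Pt(m+1)),
Lrank(p, q) = max(0, p − q + margin)
```

with Adam (learning rate 5e-5, batch 16, exponential decay 0.96/epoch,
dropout 0.45, early stopping with patience 20). After training, the five
pooling-level predictors are fused by soft voting
`f = ω1 f1 + … + ω5 f5`, the convex weights found by particle swarm
optimisation with adaptive inertia
`ω(t) = (ωmax − ωmin) Ps(t) + ωmin`, where `Ps(t)` is the fraction of
particles that improved in the previous iteration. Evaluation reports
macro precision, macro recall, macro F1, accuracy, and the geometric mean
of per-class sensitivities with zeros floored at 0.001.

## A worked example

```r
library(pestcascade)

# a 4-class synthetic benchmark: each image hides one class-coloured,
# class-oriented grating patch in clutter
spec <- scene_spec(image_size = 64, n_classes = 4, seed = 1)
data <- generate_dataset(spec, n_train = 200, n_validation = 100,
                         n_test = 35)

model <- init_cascade(backbone_config(), seed = 2)
fit <- train_cascade(model, data, train_config(max_epochs = 15, seed = 3),
                     verbose = TRUE)

val <- collect_pool_probs(fit$model, data$validation)
pso <- optimize_weights(val$pool_probs, val$labels, swarm_config(seed = 4))
ev <- evaluate_model(fit$model, data$test, fusion_weights = pso$weights)
ev$report
```

The equivalent packaged run, `run_desk_experiment(seed = 1)`, prints one
line per epoch and ends with (abridged):

```
epoch 15 lr 2.82e-05 loss 3.1454 val_acc 0.838 iou 0.220 gap -0.160 (14.2s)
untrained acc: 0.25  fused test acc: 0.8357143
```

Here `fused test acc` is the PSO-weighted soft vote on the held-out test
split (0.836 versus the untrained baseline's 0.25, which is exact because
untrained heads predict uniform probabilities and ties break to class 0
on balanced data); `iou` is the mean overlap between scale-1 attention
boxes and the planted truth boxes on validation; `gap` is the mean
true-class confidence difference Pt(3) − Pt(1) that the ranking loss
acts on. `ablate_scales()` reproduces the scale-subset comparison
(singletons, pairs, full cascade) as a five-metric table.

A thin command-line front end with the same verbs (`generate`, `train`,
`fuse`, `evaluate`, `ablation`, `report`, `selftest`) is installed at
`inst/cli/pestcascade`.

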