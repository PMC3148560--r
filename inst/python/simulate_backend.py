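"""Coalescent simulation backend: writes ms-format replicates.

Reads a scenario JSON, simulates `n` replicates with msprime and writes
them as consecutive ms-format blocks plus a JSON metadata array (one
record per replicate: seed, attempts, 0-based index of the causal site
among the segregating sites or -1, causal sample frequency).

Selection is a genic sweep at the sequence midpoint (fitness 1, 1+s/2,
1+s) conditioned by rejection on the sampled derived frequency of the
causal site lying in target_freq_range. The causal derived allele is read
off the marginal tree at the sweep position: the node whose sample-leaf
fraction is closest to the sweep's end frequency defines the carriers.

Population-scaled parameters follow the 4Ne convention: per-generation
mutation rate = theta/(4 Ne), recombination rate = rho/(4 Ne); samples
are sample_size/2 diploid individuals = sample_size chromosomes.
"""

import argparse
import json
import sys

import msprime

MOD = 2_147_483_629  # largest prime < 2^31; derived seeds stay 32-bit


def derive_seed(base, rep, attempt):
    return (base * 69069 + rep * 1_000_003 + attempt * 7919) % MOD + 1


def build_demography(spec):
    ne = spec["Ne"]
    two_ne = 2.0 * ne
    dem = msprime.Demography()
    model = spec["model"]
    if model == "panmictic":
        dem.add_population(initial_size=ne)
    elif model == "island":
        dem.add_population(name="deme0", initial_size=ne)
        dem.add_population(name="deme1", initial_size=ne)
        # 4Nm with per-deme size Ne
        m = spec["migration4Nm"] / (4.0 * ne)
        dem.set_symmetric_migration_rate(["deme0", "deme1"], m)
    elif model == "growth":
        # constant present size for the recent epoch (the sweep model
        # cannot run while the size is changing), exponential growth
        # from the ancestral size in the older epoch
        t1 = spec.get("growthLag", 0.1) * two_ne
        t2 = spec["growthStart"] * two_ne
        frac = spec["ancestralSizeFraction"]
        import math
        alpha = math.log(1.0 / frac) / (t2 - t1)
        dem.add_population(initial_size=ne)
        dem.add_population_parameters_change(
            time=t1, growth_rate=alpha)
        dem.add_population_parameters_change(
            time=t2, initial_size=frac * ne, growth_rate=0.0)
    elif model == "bottleneck":
        dem.add_population(initial_size=ne)
        dem.add_population_parameters_change(
            time=spec["bottleneckStart"] * two_ne,
            initial_size=spec["bottleneckDepth"] * ne)
        dem.add_population_parameters_change(
            time=spec["bottleneckEnd"] * two_ne, initial_size=ne)
    else:
        raise ValueError("unknown model: " + model)
    return dem


def sweep_model(spec):
    ne = spec["Ne"]
    s = spec["selection2Ns"] / (2.0 * ne)
    return msprime.SweepGenicSelection(
        position=spec["sequenceLength"] / 2.0,
        start_frequency=1.0 / (2.0 * ne),
        end_frequency=spec["endFrequency"],
        s=s,
        dt=1.0 / (40.0 * ne),
    )


def causal_carriers(ts, position, end_freq, lo, hi):
    """Carrier sample set from the marginal tree at the sweep position.

    Returns (carriers, freq) or None if no node's sample fraction falls in
    [lo, hi]."""
    tree = ts.at(position)
    n = ts.num_samples
    best, best_d = None, 2.0
    for u in tree.nodes():
        k = tree.num_samples(u)
        f = k / n
        if lo <= f <= hi:
            d = abs(f - end_freq)
            if d < best_d:
                best, best_d = u, d
    if best is None:
        return None
    carriers = set(tree.samples(best))
    return carriers, len(carriers) / n


def simulate_one(spec, seed):
    ne = spec["Ne"]
    L = spec["sequenceLength"]
    n_dip = spec["sampleSize"] // 2
    mu = spec["theta"] / (4.0 * ne)
    r = spec["rho"] / (4.0 * ne)
    dem = build_demography(spec)
    if spec["model"] == "island":
        half = n_dip // 2
        samples = {"deme0": half, "deme1": n_dip - half}
    else:
        samples = n_dip

    selected = spec["selection2Ns"] > 0
    model = ([sweep_model(spec), msprime.StandardCoalescent()]
             if selected else msprime.StandardCoalescent())
    ts = msprime.sim_ancestry(
        samples=samples, demography=dem, ploidy=2,
        sequence_length=L, recombination_rate=r,
        model=model, random_seed=seed)
    ts = msprime.sim_mutations(
        ts, rate=mu, random_seed=derive_seed(seed, 0, 1),
        model=msprime.BinaryMutationModel())
    return ts


def ms_block(ts, spec, carriers):
    L = spec["sequenceLength"]
    positions = [s.position for s in ts.sites()]
    G = ts.genotype_matrix()          # sites x samples, 0/1
    rows = ["".join(map(str, G[:, j])) for j in range(ts.num_samples)]

    causal_idx = -1
    if carriers is not None:
        pos_c = L / 2.0
        # insert the causal column keeping positions sorted
        import bisect
        causal_idx = bisect.bisect_left(positions, pos_c)
        positions.insert(causal_idx, pos_c)
        for j in range(len(rows)):
            a = "1" if j in carriers else "0"
            rows[j] = rows[j][:causal_idx] + a + rows[j][causal_idx:]

    lines = ["//", "segsites: %d" % len(positions),
             "positions: " + " ".join("%.10f" % (p / L) for p in positions)]
    lines.extend(rows)
    return "\n".join(lines), causal_idx


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("--spec", required=True)
    ap.add_argument("--n", type=int, default=1)
    ap.add_argument("--seed", type=int, required=True)
    ap.add_argument("--ms-out", required=True)
    ap.add_argument("--meta-out", required=True)
    args = ap.parse_args()

    with open(args.spec) as fh:
        spec = json.load(fh)
    selected = spec["selection2Ns"] > 0
    if selected and spec["model"] == "island":
        sys.stderr.write(
            "backend limitation: the msprime sweep model supports a single "
            "deme; island-model selection needs external (msms) ms input\n")
        sys.exit(3)

    lo, hi = spec["targetFreqRange"]
    max_rejects = int(spec.get("maxRejects", 100))
    meta = []
    blocks = []
    for rep in range(args.n):
        attempt = 0
        while True:
            seed = derive_seed(args.seed, rep, attempt)
            spec["endFrequency"] = (lo + hi) / 2.0 if not selected else (
                lo + (hi - lo) * ((seed % 1000) / 999.0))
            try:
                ts = simulate_one(spec, seed)
            except msprime._msprime.LibraryError as err:
                retriable = ("during a sweep" in str(err)
                             or "parent node having a time" in str(err))
                if retriable:
                    # trajectory long enough to overlap a demographic
                    # event (or a numerically degenerate handover):
                    # reject and retry with the next seed
                    attempt += 1
                    if attempt >= max_rejects:
                        sys.stderr.write(
                            "replicate %d: %d rejections (sweep overlaps "
                            "demographic events)\n" % (rep, attempt))
                        sys.exit(4)
                    continue
                raise
            if not selected:
                block, _ = ms_block(ts, spec, None)
                meta.append({"seed": seed, "attempts": attempt + 1,
                             "causal_index": -1, "causal_freq": None,
                             "n_sites": ts.num_sites})
                blocks.append(block)
                break
            got = causal_carriers(ts, spec["sequenceLength"] / 2.0,
                                  spec["endFrequency"], lo, hi)
            if got is not None:
                carriers, freq = got
                block, cidx = ms_block(ts, spec, carriers)
                meta.append({"seed": seed, "attempts": attempt + 1,
                             "causal_index": cidx, "causal_freq": freq,
                             "n_sites": ts.num_sites + 1})
                blocks.append(block)
                break
            attempt += 1
            if attempt >= max_rejects:
                sys.stderr.write(
                    "replicate %d: %d rejections without a causal-site "
                    "frequency in [%g, %g] (acceptance rate 0/%d)\n"
                    % (rep, attempt, lo, hi, attempt))
                sys.exit(4)

    with open(args.ms_out, "w") as fh:
        fh.write("msbridge %d %d\n%d\n\n" % (spec["sampleSize"], args.n,
                                             args.seed))
        fh.write("\n".join(blocks))
        fh.write("\n")
    with open(args.meta_out, "w") as fh:
        json.dump(meta, fh)


if __name__ == "__main__":
    main()
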