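"""Arbitrary-precision somatic-labelling oracle.

Reads a TSV of paired variant records (qual, tumor/normal GL triples,
alt depths, depths) and prints one label per row.  Posteriors are
normalized 10**GL values under a flat genotype prior, computed with
mpmath at 50 significant digits; the filter and labelling rules are
re-stated here independently of the R implementation.

Usage: oracle_label.py sites.tsv min_evidence low_af min_af min_alt min_qual
"""
import sys

import mpmath as mp

mp.mp.dps = 50


def posteriors(gl):
    vals = [mp.power(10, g) for g in gl]
    tot = sum(vals)
    return [v / tot for v in vals]


def phred(p, cap=200):
    if p <= 0:
        return mp.mpf(cap)
    return min(mp.mpf(cap), -10 * mp.log10(p))


def main():
    path = sys.argv[1]
    min_evidence = mp.mpf(sys.argv[2])
    low_af = mp.mpf(sys.argv[3])
    min_af = mp.mpf(sys.argv[4])
    min_alt = mp.mpf(sys.argv[5])
    min_qual = mp.mpf(sys.argv[6])

    with open(path) as fh:
        header = fh.readline().split()
        for line in fh:
            row = dict(zip(header, line.split()))
            qual = mp.mpf(row["qual"])
            t_gl = [mp.mpf(row[k]) for k in ("t_gl_rr", "t_gl_ra", "t_gl_aa")]
            n_gl = [mp.mpf(row[k]) for k in ("n_gl_rr", "n_gl_ra", "n_gl_aa")]
            t_alt, t_dp = mp.mpf(row["t_ad_alt"]), mp.mpf(row["t_dp"])
            n_alt, n_dp = mp.mpf(row["n_ad_alt"]), mp.mpf(row["n_dp"])
            af_t = t_alt / t_dp if t_dp > 0 else mp.mpf(0)
            af_n = n_alt / n_dp if n_dp > 0 else mp.mpf(0)

            # site filters: first violated rule wins, order
            # no_coverage, min_alt_reads, min_af, min_site_qual
            if t_dp == 0 and n_dp == 0:
                print("failed_site_filter")
                continue
            if max(t_alt, n_alt) < min_alt:
                print("failed_site_filter")
                continue
            if max(af_t, af_n) < min_af:
                print("failed_site_filter")
                continue
            if qual <= min_qual:
                print("failed_site_filter")
                continue

            pt = posteriors(t_gl)
            pn = posteriors(n_gl)
            tumor_nonref = phred(1 - max(pt[1], pt[2]))
            normal_ref = phred(1 - pn[0])
            normal_nonref = phred(pn[0])

            if af_t < low_af and n_alt >= 1 and af_n < low_af:
                print("shared_low_frequency")
            elif tumor_nonref >= min_evidence and normal_ref >= min_evidence:
                print("somatic")
            elif normal_nonref >= min_evidence:
                print("germline")
            else:
                print("reference")


if __name__ == "__main__":
    main()
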