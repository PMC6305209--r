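#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// 2-bit base codes; anything outside ACGT (incl. N) gets -1 and never matches,
// not even itself.
static inline int base_code(char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
    }
}

static inline char comp_base(char c) {
    switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
    }
}

static std::string revcomp(const std::string &s) {
    std::string r(s.rbegin(), s.rend());
    for (size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
    return r;
}

// Hamming distance with early exit; returns max_mm + 1 as soon as the budget
// is exceeded.  A position where either base is outside ACGT always counts
// as a mismatch.
static inline int hamming_at(const std::string &g, int pos,
                             const std::string &s, int max_mm) {
    int mm = 0;
    const int k = (int) s.size();
    for (int j = 0; j < k; ++j) {
        char a = g[pos + j], b = s[j];
        if (a == b && base_code(a) >= 0) continue;
        if (++mm > max_mm) return mm;
    }
    return mm;
}

// Exact-match index of Q-grams (Q fixed at 6 -> 4096 buckets) used to seed
// the pigeonhole search.  Q-grams containing non-ACGT characters are not
// indexed; they can never anchor an exact block match.
static const int QGRAM = 6;

struct QGramIndex {
    std::vector< std::vector<int> > buckets;
    void build(const std::string &seq) {
        buckets.assign(1 << (2 * QGRAM), std::vector<int>());
        const int L = (int) seq.size();
        if (L < QGRAM) return;
        uint32_t key = 0;
        int valid = 0; // run length of valid bases ending at i
        for (int i = 0; i < L; ++i) {
            int c = base_code(seq[i]);
            if (c < 0) { valid = 0; key = 0; continue; }
            key = ((key << 2) | (uint32_t) c) & ((1u << (2 * QGRAM)) - 1u);
            if (++valid >= QGRAM) buckets[key].push_back(i - QGRAM + 1);
        }
    }
};

static inline bool encode_qgram(const std::string &s, int off, uint32_t &key) {
    key = 0;
    for (int j = 0; j < QGRAM; ++j) {
        int c = base_code(s[off + j]);
        if (c < 0) return false;
        key = (key << 2) | (uint32_t) c;
    }
    return true;
}

// Collect all placements of query string s (already oriented) on one
// chromosome, Hamming distance <= max_mm.  Uses pigeonhole seeding when the
// block length supports the Q-gram index, otherwise scans every offset.
static void search_one(const std::string &g, const QGramIndex &idx,
                       const std::string &s, int max_mm,
                       std::vector<int> &starts, std::vector<int> &mms) {
    const int k = (int) s.size();
    const int L = (int) g.size();
    if (k > L) return;
    const int n_blocks = max_mm + 1;
    const int b = k / n_blocks;

    if (b < QGRAM) { // short blocks: direct scan
        for (int p = 0; p <= L - k; ++p) {
            int mm = hamming_at(g, p, s, max_mm);
            if (mm <= max_mm) { starts.push_back(p); mms.push_back(mm); }
        }
        return;
    }

    // pigeonhole: any hit with <= max_mm mismatches matches at least one of
    // the n_blocks blocks exactly, hence its leading Q-gram exactly.
    std::vector<int> cand;
    int off = 0;
    const int rem = k % n_blocks;
    for (int blk = 0; blk < n_blocks; ++blk) {
        int len = b + (blk < rem ? 1 : 0);
        uint32_t key;
        if (encode_qgram(s, off, key)) {
            for (int pos : idx.buckets[key]) {
                int p = pos - off;
                if (p >= 0 && p <= L - k) cand.push_back(p);
            }
        }
        off += len;
    }
    std::sort(cand.begin(), cand.end());
    cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
    for (int p : cand) {
        int mm = hamming_at(g, p, s, max_mm);
        if (mm <= max_mm) { starts.push_back(p); mms.push_back(mm); }
    }
}

// [[Rcpp::export]]
DataFrame cpp_align_batch(CharacterVector queries, CharacterVector chrom_seqs,
                          int max_mismatches) {
    const int n_chrom = chrom_seqs.size();
    std::vector<std::string> seqs(n_chrom);
    std::vector<QGramIndex> idx(n_chrom);
    for (int c = 0; c < n_chrom; ++c) {
        seqs[c] = as<std::string>(chrom_seqs[c]);
        idx[c].build(seqs[c]);
    }

    std::vector<int> out_q, out_c, out_s, out_m;
    std::vector<int> out_strand; // 1 = '+', 0 = '-'

    for (int qi = 0; qi < (int) queries.size(); ++qi) {
        std::string fwd = as<std::string>(queries[qi]);
        if (fwd.empty()) stop("empty k-mer at position %d", qi + 1);
        std::string rev = revcomp(fwd);
        for (int c = 0; c < n_chrom; ++c) {
            for (int strand = 1; strand >= 0; --strand) {
                const std::string &s = strand ? fwd : rev;
                std::vector<int> starts, mms;
                search_one(seqs[c], idx[c], s, max_mismatches, starts, mms);
                for (size_t h = 0; h < starts.size(); ++h) {
                    out_q.push_back(qi + 1);
                    out_c.push_back(c + 1);
                    out_s.push_back(starts[h]);
                    out_strand.push_back(strand);
                    out_m.push_back(mms[h]);
                }
            }
        }
    }

    return DataFrame::create(
        _["query"] = wrap(out_q),
        _["chrom_idx"] = wrap(out_c),
        _["start"] = wrap(out_s),
        _["fwd"] = wrap(out_strand),
        _["mismatches"] = wrap(out_m));
}
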