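#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// 2-bit base encoding; anything outside A/C/G/T (e.g. N) gets -1 and breaks
// k-mer seeds at that position.
static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

typedef std::unordered_map<std::uint64_t, std::vector<int> > KmerIndex;

// Index every k-mer of `seq` (k <= 31 so the 2-bit code fits in 64 bits).
static void index_kmers(const std::string& seq, int k, KmerIndex& idx) {
  const int n = (int) seq.size();
  if (n < k) return;
  const std::uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  std::uint64_t kmer = 0;
  int run = 0;  // number of valid consecutive bases accumulated
  for (int i = 0; i < n; ++i) {
    int c = base_code(seq[i]);
    if (c < 0) { run = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (std::uint64_t) c) & mask;
    if (++run >= k) idx[kmer].push_back(i - k + 1);
  }
}

// Ungapped full-length score of `read` placed at `offset` on `genome`.
static double score_at(const std::string& read, const std::string& genome,
                       int offset, double match, double mismatch) {
  double s = 0.0;
  const int L = (int) read.size();
  for (int i = 0; i < L; ++i) {
    char a = read[i], b = genome[offset + i];
    // an ambiguous base never matches
    if (a == b && base_code(a) >= 0) s += match; else s += mismatch;
  }
  return s;
}

// Seed-and-extend alignment of each read against each genome: shared k-mers
// propose diagonal offsets, each offset is scored as a full-length ungapped
// alignment, and the genome's best positive score is reported.
// [[Rcpp::export(name = ".kmer_align_cpp")]]
DataFrame kmer_align_cpp(CharacterVector read_seqs, CharacterVector genome_seqs,
                         int k, double match, double mismatch) {
  const int n_reads = read_seqs.size();
  const int n_genomes = genome_seqs.size();
  if (k < 1 || k > 31) stop("k must be in [1, 31]");

  std::vector<std::string> genomes(n_genomes);
  std::vector<KmerIndex> index(n_genomes);
  for (int g = 0; g < n_genomes; ++g) {
    genomes[g] = as<std::string>(genome_seqs[g]);
    index_kmers(genomes[g], k, index[g]);
  }

  std::vector<int> out_read, out_genome;
  std::vector<double> out_score;
  const std::uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  std::vector<std::uint64_t> read_kmers;
  std::vector<int> read_kpos;
  std::vector<int> offsets;

  for (int r = 0; r < n_reads; ++r) {
    const std::string read = as<std::string>(read_seqs[r]);
    const int L = (int) read.size();
    if (L < k) continue;

    read_kmers.clear(); read_kpos.clear();
    std::uint64_t kmer = 0; int run = 0;
    for (int i = 0; i < L; ++i) {
      int c = base_code(read[i]);
      if (c < 0) { run = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (std::uint64_t) c) & mask;
      if (++run >= k) { read_kmers.push_back(kmer); read_kpos.push_back(i - k + 1); }
    }
    if (read_kmers.empty()) continue;

    for (int g = 0; g < n_genomes; ++g) {
      const int glen = (int) genomes[g].size();
      if (glen < L) continue;  // read cannot be placed full-length
      offsets.clear();
      const KmerIndex& idx = index[g];
      for (size_t j = 0; j < read_kmers.size(); ++j) {
        KmerIndex::const_iterator it = idx.find(read_kmers[j]);
        if (it == idx.end()) continue;
        const std::vector<int>& pos = it->second;
        for (size_t p = 0; p < pos.size(); ++p) {
          int off = pos[p] - read_kpos[j];
          if (off >= 0 && off <= glen - L) offsets.push_back(off);
        }
      }
      if (offsets.empty()) continue;
      std::sort(offsets.begin(), offsets.end());
      offsets.erase(std::unique(offsets.begin(), offsets.end()), offsets.end());

      double best = 0.0; bool any = false;
      for (size_t j = 0; j < offsets.size(); ++j) {
        double s = score_at(read, genomes[g], offsets[j], match, mismatch);
        if (!any || s > best) { best = s; any = true; }
      }
      if (any && best > 0.0) {
        out_read.push_back(r + 1);
        out_genome.push_back(g + 1);
        out_score.push_back(best);
      }
    }
    if ((r & 0x3FF) == 0) Rcpp::checkUserInterrupt();
  }

  return DataFrame::create(_["read"] = out_read,
                           _["genome"] = out_genome,
                           _["score"] = out_score);
}
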