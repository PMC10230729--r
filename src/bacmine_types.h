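#ifndef BACMINE_TYPES_H
#define BACMINE_TYPES_H

#include <unordered_map>
#include <vector>
#include <cstdint>

// Canonical k-mer index: owner > 0 is a genome number (1-based), owner < 0 a
// species number, INT32_MIN marks k-mers shared across species (ambiguous).
struct KmerIdx {
  int k;
  int n_genomes;
  std::vector<int> species; // 1-based species id per genome
  std::unordered_map<uint64_t, int32_t> map;
};

#endif
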