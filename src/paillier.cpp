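#include <Rcpp.h>
#include <openssl/bn.h>
#include <openssl/crypto.h>
#include <random>
#include <string>
#include <vector>
using namespace Rcpp;

// Paillier with the g = n + 1 convention:
//   Enc(m; r) = (1 + m*n) * r^n mod n^2,  r uniform in (0, n)
//   Dec(c)    = L(c^lambda mod n^2) * mu mod n, L(x) = (x-1)/n,
//   lambda = lcm(p-1, q-1), mu = lambda^{-1} mod n.
// Big integers cross the R boundary as lowercase hex strings.

namespace {

struct Ctx {
  BN_CTX* ctx;
  Ctx() : ctx(BN_CTX_new()) { if (!ctx) stop("BN_CTX_new failed"); }
  ~Ctx() { BN_CTX_free(ctx); }
};

struct Bn {
  BIGNUM* b;
  Bn() : b(BN_new()) { if (!b) stop("BN_new failed"); }
  explicit Bn(BIGNUM* raw) : b(raw) {}
  ~Bn() { BN_free(b); }
  Bn(const Bn&) = delete;
  Bn& operator=(const Bn&) = delete;
};

BIGNUM* from_hex(const std::string& s) {
  BIGNUM* b = NULL;
  if (s.empty() || s.find_first_not_of("0123456789abcdefABCDEF") != std::string::npos ||
      !BN_hex2bn(&b, s.c_str()))
    stop("invalid hexadecimal big integer");
  return b;
}

std::string to_hex(const BIGNUM* b) {
  char* h = BN_bn2hex(b);
  std::string s(h);
  OPENSSL_free(h);
  for (char& c : s) c = (char)tolower((unsigned char)c);
  return s;
}

std::string to_dec(const BIGNUM* b) {
  char* d = BN_bn2dec(b);
  std::string s(d);
  OPENSSL_free(d);
  return s;
}

BIGNUM* from_dec(const std::string& s) {
  BIGNUM* b = NULL;
  if (s.empty() || s.find_first_not_of("0123456789") != std::string::npos ||
      !BN_dec2bn(&b, s.c_str()))
    stop("invalid decimal big integer");
  return b;
}

// Random r in [1, n): OpenSSL CSPRNG, or mt19937_64 in the (clearly non-secure)
// seeded fixture mode.
void draw_r(BIGNUM* r, const BIGNUM* n, std::mt19937_64* rng) {
  if (rng == NULL) {
    do {
      if (!BN_rand_range(r, n)) stop("BN_rand_range failed");
    } while (BN_is_zero(r));
  } else {
    int nbytes = BN_num_bytes(n);
    std::vector<unsigned char> buf((size_t)nbytes);
    Ctx c;
    do {
      for (int i = 0; i < nbytes; ++i) buf[(size_t)i] = (unsigned char)((*rng)() & 0xff);
      BN_bin2bn(buf.data(), nbytes, r);
      BN_nnmod(r, r, n, c.ctx);
    } while (BN_is_zero(r));
  }
}

void enc_one(BIGNUM* c, const BIGNUM* m, const BIGNUM* n, const BIGNUM* n2,
             const BIGNUM* r, BN_CTX* ctx) {
  Bn gm;
  // g^m = (1+n)^m = 1 + m*n (mod n^2)
  if (!BN_mod_mul(gm.b, m, n, n2, ctx)) stop("BN_mod_mul failed");
  if (!BN_add_word(gm.b, 1)) stop("BN_add_word failed");
  Bn rn;
  if (!BN_mod_exp(rn.b, r, n, n2, ctx)) stop("BN_mod_exp failed");
  if (!BN_mod_mul(c, gm.b, rn.b, n2, ctx)) stop("BN_mod_mul failed");
}

} // namespace

// [[Rcpp::export]]
int bn_bits_cpp(std::string hex) {
  Bn b(from_hex(hex));
  return BN_num_bits(b.b);
}

// [[Rcpp::export]]
List pl_keygen_cpp(int bits) {
  Ctx c;
  Bn p, q, n;
  for (int tries = 0; tries < 64; ++tries) {
    if (!BN_generate_prime_ex(p.b, bits / 2, 0, NULL, NULL, NULL) ||
        !BN_generate_prime_ex(q.b, bits / 2, 0, NULL, NULL, NULL))
      stop("prime generation failed");
    if (BN_cmp(p.b, q.b) == 0) continue;
    if (!BN_mul(n.b, p.b, q.b, c.ctx)) stop("BN_mul failed");
    if (BN_num_bits(n.b) == bits)
      return List::create(_["n"] = to_hex(n.b), _["p"] = to_hex(p.b), _["q"] = to_hex(q.b));
  }
  stop("failed to generate a modulus of the requested size");
}

// Deterministic keypair from a seed: candidates drawn from mt19937_64, stepped
// to the next prime. Regression fixtures only, not a secure key.
// [[Rcpp::export]]
List pl_keygen_seeded_cpp(int bits, int seed) {
  Ctx c;
  std::mt19937_64 rng((uint64_t)(int64_t)seed);
  int half = bits / 2;
  int nbytes = (half + 7) / 8;
  Bn p, q, n;
  for (int tries = 0; tries < 64; ++tries) {
    for (int which = 0; which < 2; ++which) {
      BIGNUM* tgt = which == 0 ? p.b : q.b;
      std::vector<unsigned char> buf((size_t)nbytes);
      for (int i = 0; i < nbytes; ++i) buf[(size_t)i] = (unsigned char)(rng() & 0xff);
      buf[0] |= 0xC0; // top two bits: full-size prime, full-size product
      buf[(size_t)nbytes - 1] |= 1;
      BN_bin2bn(buf.data(), nbytes, tgt);
      BN_mask_bits(tgt, half);
      BN_set_bit(tgt, half - 1);
      BN_set_bit(tgt, half - 2);
      BN_set_bit(tgt, 0);
      while (BN_check_prime(tgt, c.ctx, NULL) != 1) {
        if (!BN_add_word(tgt, 2)) stop("BN_add_word failed");
      }
    }
    if (BN_cmp(p.b, q.b) == 0) continue;
    if (!BN_mul(n.b, p.b, q.b, c.ctx)) stop("BN_mul failed");
    if (BN_num_bits(n.b) == bits)
      return List::create(_["n"] = to_hex(n.b), _["p"] = to_hex(p.b), _["q"] = to_hex(q.b));
  }
  stop("failed to generate a seeded modulus of the requested size");
}

// Encrypt a vector of non-negative decimal plaintexts. seed < 0 => CSPRNG.
// [[Rcpp::export]]
CharacterVector pl_encrypt_cpp(std::string n_hex, CharacterVector m_dec, int seed) {
  Ctx c;
  Bn n(from_hex(n_hex)), n2, r, ct;
  if (!BN_sqr(n2.b, n.b, c.ctx)) stop("BN_sqr failed");
  std::mt19937_64 rng((uint64_t)(int64_t)seed);
  std::mt19937_64* prng = seed < 0 ? NULL : &rng;
  CharacterVector out(m_dec.size());
  for (R_xlen_t i = 0; i < m_dec.size(); ++i) {
    Bn m(from_dec(as<std::string>(m_dec[i])));
    if (BN_is_negative(m.b) || BN_cmp(m.b, n.b) >= 0)
      stop("plaintext out of range [0, n)");
    draw_r(r.b, n.b, prng);
    enc_one(ct.b, m.b, n.b, n2.b, r.b, c.ctx);
    out[i] = to_hex(ct.b);
  }
  return out;
}

// Encrypt a 0/1 vector (an LSH) elementwise; every position, zeros included.
// [[Rcpp::export]]
CharacterVector pl_encrypt_bits_cpp(std::string n_hex, IntegerVector bits, int seed) {
  Ctx c;
  Bn n(from_hex(n_hex)), n2, r, ct, m;
  if (!BN_sqr(n2.b, n.b, c.ctx)) stop("BN_sqr failed");
  std::mt19937_64 rng((uint64_t)(int64_t)seed);
  std::mt19937_64* prng = seed < 0 ? NULL : &rng;
  CharacterVector out(bits.size());
  for (R_xlen_t i = 0; i < bits.size(); ++i) {
    if (bits[i] != 0 && bits[i] != 1) stop("LSH bits must be 0 or 1");
    if (!BN_set_word(m.b, (BN_ULONG)bits[i])) stop("BN_set_word failed");
    draw_r(r.b, n.b, prng);
    enc_one(ct.b, m.b, n.b, n2.b, r.b, c.ctx);
    out[i] = to_hex(ct.b);
  }
  return out;
}

// Encrypt one plaintext with caller-supplied randomness (test oracle hook).
// [[Rcpp::export]]
std::string pl_encrypt_with_r_cpp(std::string n_hex, std::string m_dec, std::string r_hex) {
  Ctx c;
  Bn n(from_hex(n_hex)), n2, ct;
  Bn m(from_dec(m_dec)), r(from_hex(r_hex));
  if (!BN_sqr(n2.b, n.b, c.ctx)) stop("BN_sqr failed");
  if (BN_cmp(m.b, n.b) >= 0) stop("plaintext out of range [0, n)");
  if (BN_is_zero(r.b) || BN_cmp(r.b, n.b) >= 0) stop("r out of range (0, n)");
  enc_one(ct.b, m.b, n.b, n2.b, r.b, c.ctx);
  return to_hex(ct.b);
}

// Homomorphic addition: elementwise ciphertext product mod n^2.
// [[Rcpp::export]]
CharacterVector pl_add_cpp(std::string n_hex, CharacterVector c1, CharacterVector c2) {
  if (c1.size() != c2.size()) stop("ciphertext vectors must have equal length");
  Ctx c;
  Bn n(from_hex(n_hex)), n2, out_b;
  if (!BN_sqr(n2.b, n.b, c.ctx)) stop("BN_sqr failed");
  CharacterVector out(c1.size());
  for (R_xlen_t i = 0; i < c1.size(); ++i) {
    Bn a(from_hex(as<std::string>(c1[i]))), b(from_hex(as<std::string>(c2[i])));
    if (BN_cmp(a.b, n2.b) >= 0 || BN_cmp(b.b, n2.b) >= 0)
      stop("ciphertext out of range [0, n^2)");
    if (!BN_mod_mul(out_b.b, a.b, b.b, n2.b, c.ctx)) stop("BN_mod_mul failed");
    out[i] = to_hex(out_b.b);
  }
  return out;
}

// Homomorphic sum of the supplied ciphertexts, re-randomized with a fresh E(0)
// so empty selections still return a valid, fresh ciphertext.
// [[Rcpp::export]]
std::string pl_sum_cpp(std::string n_hex, CharacterVector cts, int seed) {
  Ctx c;
  Bn n(from_hex(n_hex)), n2, acc, r, zero;
  if (!BN_sqr(n2.b, n.b, c.ctx)) stop("BN_sqr failed");
  std::mt19937_64 rng((uint64_t)(int64_t)seed);
  std::mt19937_64* prng = seed < 0 ? NULL : &rng;
  draw_r(r.b, n.b, prng);
  if (!BN_set_word(zero.b, 0)) stop("BN_set_word failed");
  enc_one(acc.b, zero.b, n.b, n2.b, r.b, c.ctx); // fresh E(0)
  for (R_xlen_t i = 0; i < cts.size(); ++i) {
    Bn ci(from_hex(as<std::string>(cts[i])));
    if (BN_cmp(ci.b, n2.b) >= 0) stop("ciphertext out of range [0, n^2)");
    if (!BN_mod_mul(acc.b, acc.b, ci.b, n2.b, c.ctx)) stop("BN_mod_mul failed");
  }
  return to_hex(acc.b);
}

// [[Rcpp::export]]
CharacterVector pl_decrypt_cpp(std::string n_hex, std::string p_hex, std::string q_hex,
                               CharacterVector c_hex) {
  Ctx c;
  Bn n(from_hex(n_hex)), p(from_hex(p_hex)), q(from_hex(q_hex));
  Bn n2, pq, p1, q1, g, lambda, mu, t, m;
  if (!BN_mul(pq.b, p.b, q.b, c.ctx)) stop("BN_mul failed");
  if (BN_cmp(pq.b, n.b) != 0) stop("private key does not match the public modulus");
  if (!BN_sqr(n2.b, n.b, c.ctx)) stop("BN_sqr failed");
  if (!BN_copy(p1.b, p.b) || !BN_sub_word(p1.b, 1)) stop("BN arithmetic failed");
  if (!BN_copy(q1.b, q.b) || !BN_sub_word(q1.b, 1)) stop("BN arithmetic failed");
  // lambda = lcm(p-1, q-1) = (p-1)(q-1)/gcd(p-1, q-1)
  if (!BN_gcd(g.b, p1.b, q1.b, c.ctx)) stop("BN_gcd failed");
  if (!BN_mul(lambda.b, p1.b, q1.b, c.ctx)) stop("BN_mul failed");
  if (!BN_div(lambda.b, NULL, lambda.b, g.b, c.ctx)) stop("BN_div failed");
  if (!BN_mod_inverse(mu.b, lambda.b, n.b, c.ctx))
    stop("lambda is not invertible mod n: invalid key");
  CharacterVector out(c_hex.size());
  for (R_xlen_t i = 0; i < c_hex.size(); ++i) {
    Bn ct(from_hex(as<std::string>(c_hex[i])));
    if (BN_is_zero(ct.b) || BN_cmp(ct.b, n2.b) >= 0)
      stop("malformed ciphertext: out of range (0, n^2)");
    if (!BN_mod_exp(t.b, ct.b, lambda.b, n2.b, c.ctx)) stop("BN_mod_exp failed");
    // L(t) = (t - 1) / n
    if (!BN_sub_word(t.b, 1)) stop("BN_sub_word failed");
    if (!BN_div(t.b, NULL, t.b, n.b, c.ctx)) stop("BN_div failed");
    if (!BN_mod_mul(m.b, t.b, mu.b, n.b, c.ctx)) stop("BN_mod_mul failed");
    out[i] = to_dec(m.b);
  }
  return out;
}
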