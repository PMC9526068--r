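// Arbitrary-precision rational arithmetic backend.
//
// Values cross the R boundary as canonical decimal strings "p" or "p/q"
// (lowest terms, q > 0); boost::multiprecision::cpp_rational keeps the
// canonical form after every operation.

#include <Rcpp.h>
#include <boost/multiprecision/cpp_int.hpp>

using boost::multiprecision::cpp_int;
using boost::multiprecision::cpp_rational;

static cpp_rational parse_rat(const std::string& s) {
  std::size_t slash = s.find('/');
  if (slash == std::string::npos) {
    return cpp_rational(cpp_int(s));
  }
  cpp_int num(s.substr(0, slash));
  cpp_int den(s.substr(slash + 1));
  if (den == 0) Rcpp::stop("rational with zero denominator: '%s'", s.c_str());
  return cpp_rational(num, den);
}

static std::string format_rat(const cpp_rational& q) {
  std::string out = numerator(q).str();
  if (denominator(q) != 1) {
    out += "/";
    out += denominator(q).str();
  }
  return out;
}

// [[Rcpp::export(name = ".rat_arith")]]
Rcpp::CharacterVector rat_arith(int op, Rcpp::CharacterVector x,
                                Rcpp::CharacterVector y) {
  R_xlen_t nx = x.size(), ny = y.size();
  R_xlen_t n = std::max(nx, ny);
  if (nx == 0 || ny == 0) return Rcpp::CharacterVector(0);
  Rcpp::CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    cpp_rational a = parse_rat(Rcpp::as<std::string>(x[i % nx]));
    cpp_rational b = parse_rat(Rcpp::as<std::string>(y[i % ny]));
    cpp_rational r;
    switch (op) {
      case 1: r = a + b; break;
      case 2: r = a - b; break;
      case 3: r = a * b; break;
      case 4:
        if (b == 0) Rcpp::stop("exact division by zero");
        r = a / b;
        break;
      default: Rcpp::stop("unknown arithmetic opcode");
    }
    out[i] = format_rat(r);
  }
  return out;
}

// [[Rcpp::export(name = ".rat_pow")]]
Rcpp::CharacterVector rat_pow(Rcpp::CharacterVector x, Rcpp::IntegerVector e) {
  R_xlen_t nx = x.size(), ne = e.size();
  R_xlen_t n = std::max(nx, ne);
  if (nx == 0 || ne == 0) return Rcpp::CharacterVector(0);
  Rcpp::CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    cpp_rational a = parse_rat(Rcpp::as<std::string>(x[i % nx]));
    int k = e[i % ne];
    bool inv = k < 0;
    if (inv) {
      if (a == 0) Rcpp::stop("exact division by zero");
      k = -k;
    }
    cpp_rational r = 1;
    cpp_rational base = a;
    while (k > 0) {  // binary exponentiation
      if (k & 1) r *= base;
      k >>= 1;
      if (k) base *= base;
    }
    if (inv) r = cpp_rational(1) / r;
    out[i] = format_rat(r);
  }
  return out;
}

// Three-way comparison: -1, 0, 1.
// [[Rcpp::export(name = ".rat_cmp")]]
Rcpp::IntegerVector rat_cmp(Rcpp::CharacterVector x, Rcpp::CharacterVector y) {
  R_xlen_t nx = x.size(), ny = y.size();
  R_xlen_t n = std::max(nx, ny);
  if (nx == 0 || ny == 0) return Rcpp::IntegerVector(0);
  Rcpp::IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    cpp_rational a = parse_rat(Rcpp::as<std::string>(x[i % nx]));
    cpp_rational b = parse_rat(Rcpp::as<std::string>(y[i % ny]));
    out[i] = (a < b) ? -1 : (a == b ? 0 : 1);
  }
  return out;
}

// [[Rcpp::export(name = ".rat_to_double")]]
Rcpp::NumericVector rat_to_double(Rcpp::CharacterVector x) {
  Rcpp::NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    cpp_rational a = parse_rat(Rcpp::as<std::string>(x[i]));
    out[i] = a.convert_to<double>();
  }
  return out;
}

// Canonicalise "p/q" strings (reduce, normalise sign); validates input.
// [[Rcpp::export(name = ".rat_canonical")]]
Rcpp::CharacterVector rat_canonical(Rcpp::CharacterVector x) {
  Rcpp::CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    out[i] = format_rat(parse_rat(Rcpp::as<std::string>(x[i])));
  }
  return out;
}

// Exact generalised harmonic sum S_{p,n} = sum_{k=1}^n k^{-p}.
// [[Rcpp::export(name = ".rat_harmonic")]]
std::string rat_harmonic(int p, int n) {
  if (p < 1) Rcpp::stop("harmonic order p must be >= 1");
  if (n < 0) Rcpp::stop("harmonic upper limit n must be >= 0");
  cpp_rational s = 0;
  for (int k = 1; k <= n; ++k) {
    cpp_int kp = 1;
    for (int j = 0; j < p; ++j) kp *= k;
    s += cpp_rational(cpp_int(1), kp);
  }
  return format_rat(s);
}
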