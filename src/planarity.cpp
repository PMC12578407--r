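#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <functional>
using namespace Rcpp;

// Planarity testing for simple undirected graphs.
//
// Strategy: decompose into biconnected components (a graph is planar iff
// every biconnected component is planar), then run Demoucron's incremental
// face-embedding algorithm on each component. Component sizes in this
// package are module-scale (tens to a few hundred vertices), where the
// O(V*E) per-iteration fragment scan is negligible.

namespace {

struct Fragment {
  bool chord;                 // single unembedded edge with both ends embedded
  int edge_id;                // valid when chord
  int comp_rep;               // representative unembedded vertex otherwise
  std::vector<int> attach;    // sorted, deduplicated attachment vertices
  std::vector<int> adm;       // admissible face indices
};

// Demoucron on one biconnected component. Vertices are 0..n-1 local ids.
bool demoucron_biconnected(int n, const std::vector<std::pair<int, int>> &edges) {
  const int m = static_cast<int>(edges.size());
  // Smallest non-planar graphs (subdivisions of K5/K3,3) need >= 9 edges.
  if (n <= 4 || m <= 8) return true;
  if (m > 3 * n - 6) return false;

  std::vector<std::vector<std::pair<int, int>>> adj(n); // (neighbor, edge id)
  for (int e = 0; e < m; ++e) {
    adj[edges[e].first].push_back(std::make_pair(edges[e].second, e));
    adj[edges[e].second].push_back(std::make_pair(edges[e].first, e));
  }

  // --- find an initial cycle by DFS (exists: biconnected, n >= 3) ---
  std::vector<int> parent(n, -1), parent_edge(n, -1), state(n, 0), order;
  std::vector<int> cycle;
  {
    std::vector<std::pair<int, int>> stack; // (vertex, adj position)
    stack.push_back(std::make_pair(0, 0));
    state[0] = 1;
    while (!stack.empty() && cycle.empty()) {
      int v = stack.back().first;
      int &pos = stack.back().second;
      if (pos >= static_cast<int>(adj[v].size())) {
        state[v] = 2;
        stack.pop_back();
        continue;
      }
      int w = adj[v][pos].first;
      int e = adj[v][pos].second;
      ++pos;
      if (e == parent_edge[v]) continue;
      if (state[w] == 1) { // back edge -> cycle w .. v
        int u = v;
        while (u != w) {
          cycle.push_back(u);
          u = parent[u];
        }
        cycle.push_back(w);
        std::reverse(cycle.begin(), cycle.end());
      } else if (state[w] == 0) {
        state[w] = 1;
        parent[w] = v;
        parent_edge[w] = e;
        stack.push_back(std::make_pair(w, 0));
      }
    }
  }
  if (cycle.size() < 3) return true; // no cycle: tree, planar

  std::vector<char> emb_v(n, 0), emb_e(m, 0);
  // edge lookup for marking: map (min,max) -> edge ids via adjacency scan
  auto mark_edge = [&](int u, int v) {
    for (size_t i = 0; i < adj[u].size(); ++i)
      if (adj[u][i].first == v) { emb_e[adj[u][i].second] = 1; return; }
  };
  for (size_t i = 0; i < cycle.size(); ++i) {
    emb_v[cycle[i]] = 1;
    mark_edge(cycle[i], cycle[(i + 1) % cycle.size()]);
  }

  std::vector<std::vector<int>> faces;
  faces.push_back(cycle);
  std::vector<int> rev(cycle.rbegin(), cycle.rend());
  faces.push_back(rev);

  int n_embedded_edges = 0;
  for (int e = 0; e < m; ++e) n_embedded_edges += emb_e[e];

  std::vector<int> comp(n);
  while (n_embedded_edges < m) {
    // --- fragments ---
    std::vector<Fragment> frags;
    // chords
    for (int e = 0; e < m; ++e) {
      if (emb_e[e]) continue;
      int u = edges[e].first, v = edges[e].second;
      if (emb_v[u] && emb_v[v]) {
        Fragment f;
        f.chord = true;
        f.edge_id = e;
        f.comp_rep = -1;
        f.attach.push_back(std::min(u, v));
        f.attach.push_back(std::max(u, v));
        frags.push_back(f);
      }
    }
    // components of unembedded vertices
    std::fill(comp.begin(), comp.end(), -1);
    int n_comp = 0;
    for (int s = 0; s < n; ++s) {
      if (emb_v[s] || comp[s] != -1) continue;
      std::vector<int> bfs(1, s);
      comp[s] = n_comp;
      for (size_t qi = 0; qi < bfs.size(); ++qi) {
        int v = bfs[qi];
        for (size_t i = 0; i < adj[v].size(); ++i) {
          int w = adj[v][i].first;
          if (!emb_v[w] && comp[w] == -1) {
            comp[w] = n_comp;
            bfs.push_back(w);
          }
        }
      }
      Fragment f;
      f.chord = false;
      f.edge_id = -1;
      f.comp_rep = s;
      for (size_t qi = 0; qi < bfs.size(); ++qi) {
        int v = bfs[qi];
        for (size_t i = 0; i < adj[v].size(); ++i)
          if (emb_v[adj[v][i].first]) f.attach.push_back(adj[v][i].first);
      }
      std::sort(f.attach.begin(), f.attach.end());
      f.attach.erase(std::unique(f.attach.begin(), f.attach.end()), f.attach.end());
      frags.push_back(f);
      ++n_comp;
    }
    if (frags.empty()) break; // all edges embedded

    // --- admissible faces ---
    std::vector<char> in_face(n);
    int best = -1;
    for (size_t fi = 0; fi < frags.size(); ++fi) {
      Fragment &f = frags[fi];
      for (size_t k = 0; k < faces.size(); ++k) {
        std::fill(in_face.begin(), in_face.end(), 0);
        for (size_t j = 0; j < faces[k].size(); ++j) in_face[faces[k][j]] = 1;
        bool ok = true;
        for (size_t a = 0; a < f.attach.size(); ++a)
          if (!in_face[f.attach[a]]) { ok = false; break; }
        if (ok) f.adm.push_back(static_cast<int>(k));
      }
      if (f.adm.empty()) return false;
      if (best < 0 || f.adm.size() < frags[best].adm.size()) best = static_cast<int>(fi);
    }

    // --- alpha path through the chosen fragment ---
    Fragment &f = frags[best];
    std::vector<int> path;       // vertices a .. b
    std::vector<int> path_edges; // edge ids along path
    if (f.chord) {
      path.push_back(edges[f.edge_id].first);
      path.push_back(edges[f.edge_id].second);
      path_edges.push_back(f.edge_id);
    } else {
      // BFS from attachment a through unembedded component vertices to
      // any other embedded attachment b != a.
      int a = f.attach[0];
      std::vector<int> prev(n, -2), prev_edge(n, -1);
      std::vector<int> queue;
      prev[a] = -1;
      // seed with component neighbors of a
      for (size_t i = 0; i < adj[a].size(); ++i) {
        int w = adj[a][i].first;
        if (!emb_v[w] && comp[w] == comp[f.comp_rep] && prev[w] == -2) {
          prev[w] = a;
          prev_edge[w] = adj[a][i].second;
          queue.push_back(w);
        }
      }
      int b = -1, b_from = -1, b_edge = -1;
      for (size_t qi = 0; qi < queue.size() && b < 0; ++qi) {
        int v = queue[qi];
        for (size_t i = 0; i < adj[v].size(); ++i) {
          int w = adj[v][i].first;
          if (emb_v[w]) {
            if (w != a) { b = w; b_from = v; b_edge = adj[v][i].second; break; }
          } else if (prev[w] == -2) {
            prev[w] = v;
            prev_edge[w] = adj[v][i].second;
            queue.push_back(w);
          }
        }
      }
      // biconnected => a second attachment is always reachable
      if (b < 0) return false;
      std::vector<int> rpath(1, b);
      std::vector<int> redges(1, b_edge);
      int u = b_from;
      while (u != -1) {
        rpath.push_back(u);
        if (prev_edge[u] >= 0) redges.push_back(prev_edge[u]);
        u = prev[u];
      }
      std::reverse(rpath.begin(), rpath.end());
      std::reverse(redges.begin(), redges.end());
      path = rpath;
      path_edges = redges;
    }

    // --- embed the path into an admissible face, splitting it ---
    int fk = f.adm[0];
    std::vector<int> &B = faces[fk];
    int ia = -1, ib = -1;
    for (size_t j = 0; j < B.size(); ++j) {
      if (B[j] == path.front()) ia = static_cast<int>(j);
      if (B[j] == path.back()) ib = static_cast<int>(j);
    }
    const int fl = static_cast<int>(B.size());
    std::vector<int> arc1, arc2; // a->b and b->a along B
    for (int j = ia; ; j = (j + 1) % fl) { arc1.push_back(B[j]); if (j == ib) break; }
    for (int j = ib; ; j = (j + 1) % fl) { arc2.push_back(B[j]); if (j == ia) break; }
    std::vector<int> interior(path.begin() + 1, path.end() - 1);
    std::vector<int> face1(arc1);
    face1.insert(face1.end(), interior.rbegin(), interior.rend());
    std::vector<int> face2(arc2);
    face2.insert(face2.end(), interior.begin(), interior.end());
    faces[fk] = face1;
    faces.push_back(face2);

    for (size_t j = 0; j < path.size(); ++j) emb_v[path[j]] = 1;
    for (size_t j = 0; j < path_edges.size(); ++j) {
      if (!emb_e[path_edges[j]]) {
        emb_e[path_edges[j]] = 1;
        ++n_embedded_edges;
      }
    }
  }
  return true;
}

} // namespace

//' @noRd
// [[Rcpp::export]]
bool cpp_is_planar(int n, IntegerMatrix edges) {
  const int m = edges.nrow();
  if (n < 0) stop("negative vertex count");
  if (m == 0) return true;

  std::vector<std::vector<std::pair<int, int>>> adj(n);
  for (int e = 0; e < m; ++e) {
    int u = edges(e, 0) - 1, v = edges(e, 1) - 1;
    if (u < 0 || v < 0 || u >= n || v >= n) stop("edge endpoint out of range");
    if (u == v) stop("self-loop not allowed");
    adj[u].push_back(std::make_pair(v, e));
    adj[v].push_back(std::make_pair(u, e));
  }

  // Hopcroft-Tarjan biconnected components (iterative, edge stack).
  std::vector<int> num(n, -1), low(n, 0), parent(n, -1);
  std::vector<std::vector<int>> components; // lists of edge ids
  std::vector<int> estack;
  int counter = 0;
  for (int root = 0; root < n; ++root) {
    if (num[root] != -1) continue;
    std::vector<std::pair<int, int>> stack;
    stack.push_back(std::make_pair(root, 0));
    num[root] = low[root] = counter++;
    while (!stack.empty()) {
      int v = stack.back().first;
      int &pos = stack.back().second;
      if (pos < static_cast<int>(adj[v].size())) {
        int w = adj[v][pos].first;
        int e = adj[v][pos].second;
        ++pos;
        if (num[w] == -1) {
          estack.push_back(e);
          parent[w] = v;
          num[w] = low[w] = counter++;
          stack.push_back(std::make_pair(w, 0));
        } else if (num[w] < num[v] && w != parent[v]) {
          estack.push_back(e);
          low[v] = std::min(low[v], num[w]);
        }
      } else {
        stack.pop_back();
        if (!stack.empty()) {
          int u = stack.back().first;
          low[u] = std::min(low[u], low[v]);
          if (low[v] >= num[u]) {
            // pop the component of edges discovered since (u, v)
            std::vector<int> compe;
            while (!estack.empty()) {
              int e = estack.back();
              int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
              if (std::max(num[a], num[b]) < num[v]) break;
              estack.pop_back();
              compe.push_back(e);
            }
            components.push_back(compe);
          }
        }
      }
    }
  }

  std::vector<int> local(n, -1);
  for (size_t c = 0; c < components.size(); ++c) {
    const std::vector<int> &ce = components[c];
    if (ce.size() <= 2) continue; // an edge or two edges: planar
    std::vector<int> verts;
    for (size_t i = 0; i < ce.size(); ++i) {
      verts.push_back(edges(ce[i], 0) - 1);
      verts.push_back(edges(ce[i], 1) - 1);
    }
    std::sort(verts.begin(), verts.end());
    verts.erase(std::unique(verts.begin(), verts.end()), verts.end());
    for (size_t i = 0; i < verts.size(); ++i) local[verts[i]] = static_cast<int>(i);
    std::vector<std::pair<int, int>> le;
    for (size_t i = 0; i < ce.size(); ++i)
      le.push_back(std::make_pair(local[edges(ce[i], 0) - 1], local[edges(ce[i], 1) - 1]));
    bool ok = demoucron_biconnected(static_cast<int>(verts.size()), le);
    for (size_t i = 0; i < verts.size(); ++i) local[verts[i]] = -1;
    if (!ok) return false;
  }
  return true;
}
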