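{"level":2,"width":18,"height":9,"walls":[[0,0],[1,0],[2,0],[3,0],[4,0],[5,0],[6,0],[7,0],[8,0],[9,0],[10,0],[11,0],[12,0],[13,0],[14,0],[15,0],[16,0],[17,0],[0,1],[17,1],[0,2],[2,2],[3,2],[4,2],[5,2],[7,2],[8,2],[9,2],[10,2],[11,2],[12,2],[14,2],[15,2],[17,2],[0,3],[17,3],[0,4],[2,4],[3,4],[5,4],[6,4],[7,4],[8,4],[9,4],[10,4],[11,4],[12,4],[14,4],[15,4],[17,4],[0,5],[17,5],[0,6],[2,6],[3,6],[5,6],[6,6],[7,6],[8,6],[10,6],[11,6],[12,6],[13,6],[15,6],[16,6],[17,6],[0,7],[17,7],[0,8],[1,8],[2,8],[3,8],[4,8],[5,8],[6,8],[7,8],[8,8],[9,8],[10,8],[11,8],[12,8],[13,8],[14,8],[15,8],[16,8],[17,8]],"start":[1,1],"finish":[[15,7],[16,7]],"zones":{"1":[[7,1]],"2":[[14,1]],"3":[[4,3]],"4":[[15,3]],"5":[[3,5]],"6":[[10,5]],"7":[[5,7]]},"checkpoints":["3","7","F"]}
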